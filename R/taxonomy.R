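#' Nine-class conjugate taxonomy
#'
#' The configuration classes assigned to single-cell IFC records of T cell /
#' B-LCL co-cultures, organized in two levels. Level 1 counts the cells in the
#' image (singlet, doublet, multiplet); level 2 names the configuration and
#' whether proximal TCR signaling (P-CD3zeta) is present. Two classes are
#' experimental artifacts: they are kept during classifier training (they
#' improve the decision boundary) but excluded from all population-level
#' analyses.
#'
#' @return An object of class `class_taxonomy`: a list with
#'   `classes` (character, length 9), `level1` (named character mapping each
#'   class to `"singlet"`, `"doublet"` or `"multiplet"`) and `artifact`
#'   (character, the classes excluded downstream).
#' @examples
#' tax <- class_taxonomy()
#' setdiff(tax$classes, tax$artifact)  # the 7 analysis classes
#' @export
class_taxonomy <- function() {
  classes <- c(
    "single B-LCL",
    "single T cell w/o signaling",
    "single T cell w/ signaling",
    "T cell w/ small B-LCL",
    "B-LCL and T cell in one layer",
    "synapse w/o signaling",
    "synapse w/ signaling",
    "no cell-cell interaction",
    "multi-synapse"
  )
  level1 <- c(
    "single B-LCL"                  = "singlet",
    "single T cell w/o signaling"   = "singlet",
    "single T cell w/ signaling"    = "singlet",
    "T cell w/ small B-LCL"         = "doublet",
    "B-LCL and T cell in one layer" = "doublet",
    "synapse w/o signaling"         = "doublet",
    "synapse w/ signaling"          = "doublet",
    "no cell-cell interaction"      = "doublet",
    "multi-synapse"                 = "multiplet"
  )
  artifact <- c("T cell w/ small B-LCL", "no cell-cell interaction")
  structure(
    list(classes = classes, level1 = level1, artifact = artifact),
    class = "class_taxonomy"
  )
}

#' @export
print.class_taxonomy <- function(x, ...) {
  cat("Conjugate class taxonomy (", length(x$classes), " classes)\n", sep = "")
  for (cl in x$classes) {
    tag <- if (cl %in% x$artifact) " [artifact]" else ""
    cat(sprintf("  %-30s %s%s\n", cl, x$level1[[cl]], tag))
  }
  invisible(x)
}

#' Analysis classes (taxonomy minus artifacts)
#' @param taxonomy a [class_taxonomy()] object.
#' @return Character vector of the non-artifact classes, in taxonomy order.
#' @export
analysis_classes <- function(taxonomy = class_taxonomy()) {
  setdiff(taxonomy$classes, taxonomy$artifact)
}

#' Default channel panel
#'
#' Channel names used throughout: brightfield, F-actin (cytoskeleton), MHCII
#' (B cell marker), CD3 (T cell marker), phosphorylated CD3 zeta (TCR
#' signaling) and the viability stain.
#'
#' @param viability include the Live/Dead channel (default `TRUE`).
#' @return Character vector of channel names.
#' @export
default_panel <- function(viability = TRUE) {
  ch <- c("BF", "Factin", "MHCII", "CD3", "PCD3z")
  if (viability) ch <- c(ch, "LiveDead")
  ch
}

#' Fluorescent channels of a panel (everything except BF and viability)
#' @param panel character vector of channel names.
#' @return Character vector.
#' @export
fluorescent_channels <- function(panel = default_panel()) {
  setdiff(panel, c("BF", "LiveDead"))
}
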