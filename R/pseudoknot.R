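#' Detect an H-type pseudoknot
#'
#' Searches the restricted two-crossing-helix (H-type / simple recursive)
#' class: helices `H1 = (i+t, j-t)` and `H2 = (k+t, l-t)` with
#' `i < k < j < l`, each of at least `min_helix` contiguous allowed pairs,
#' scored as the sum of both helices' model energies (`bp` mode: -1 per
#' pair). The best-scoring configuration is reported as a pseudoknot when its
#' energy reaches `pk_threshold` (default -6 in `bp` mode, i.e. at least six
#' pairs across the two helices).
#'
#' @param residues residue string (a candidate interval, not a whole genome).
#' @param model an [energy_model()].
#' @param min_helix minimum pairs per helix (guards against spurious 1-2 bp
#'   "helices").
#' @param pk_threshold report a pseudoknot when the best energy is `<=` this.
#' @return object of class `pk_result`: `has_pk`, `pk_energy` (0 when
#'   `has_pk` is `FALSE`), `structure` (an [arc_annotated()] with the two
#'   crossing helix layers; empty structure when no pseudoknot).
#' @export
detect_pseudoknot <- function(residues, model = energy_model("bp"),
                              min_helix = 3L, pk_threshold = -6) {
  stopifnot(inherits(model, "energy_model"), min_helix >= 1L)
  res <- normalize_rna(residues)
  empty <- function() {
    structure(list(has_pk = FALSE, pk_energy = 0,
                   structure = arc_annotated(res)), class = "pk_result")
  }
  if (nchar(res) < 2L * (2L * min_helix) + 2L) return(empty())
  out <- .cpp_pknot(res_to_int(res), if (model$mode == "bp") 0L else 1L,
                    model$stack, as.integer(min_helix), model$min_loop)
  if (!out$found || out$energy > pk_threshold) return(empty())
  structure(list(has_pk = TRUE, pk_energy = out$energy,
                 structure = arc_annotated(res, rbind(out$helix1, out$helix2))),
            class = "pk_result")
}

#' @export
print.pk_result <- function(x, ...) {
  if (x$has_pk) {
    cat(sprintf("<pk_result> pseudoknot, energy %.2f (%d pairs)\n",
                x$pk_energy, NROW(x$structure$arcs)))
  } else {
    cat("<pk_result> no pseudoknot\n")
  }
  invisible(x)
}
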