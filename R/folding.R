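PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

res_to_int <- function(residues) {
  match(strsplit(residues, "", fixed = TRUE)[[1]], RNA_ALPHABET) - 1L
}

#' Energy model for folding and pseudoknot scoring
#'
#' Two modes are supported. `"bp"` scores -1 per base pair and 0 otherwise
#' (base-pair maximisation expressed as an energy, exactly testable against
#' enumeration). `"nn"` is a stacking-only nearest-neighbour model: each pair
#' scores 0 and each stack of adjacent pairs scores the tabulated stacking
#' energy (kcal/mol); hairpin and internal loops score 0. Allowed pairs are
#' `AU, UA, GC, CG, GU, UG` in both modes; the minimum hairpin loop is
#' `min_loop` unpaired bases.
#'
#' @param mode `"bp"` or `"nn"`.
#' @param params path to a stacking parameter file (lines `pair1 pair2 energy`,
#'   pairs written 5'-3' as e.g. `GC`), or `NULL` for the packaged table.
#'   Unlisted stacks score 0.
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return object of class `energy_model`.
#' @export
energy_model <- function(mode = c("bp", "nn"), params = NULL, min_loop = 3L) {
  mode <- match.arg(mode)
  stopifnot(min_loop >= 0L)
  stack <- matrix(0, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  if (mode == "nn") {
    if (is.null(params)) {
      params <- system.file("extdata", "stack_energies.txt",
                            package = "iresscan", mustWork = TRUE)
    }
    tab <- utils::read.table(params, header = FALSE, comment.char = "#",
                             col.names = c("outer", "inner", "energy"),
                             stringsAsFactors = FALSE)
    bad <- !(tab$outer %in% PAIR_TYPES & tab$inner %in% PAIR_TYPES)
    if (any(bad)) stop("unknown pair type in stacking parameter file", call. = FALSE)
    if (any(!is.finite(tab$energy)))
      stop("non-finite stacking energy", call. = FALSE)
    stack[cbind(tab$outer, tab$inner)] <- tab$energy
  }
  structure(list(mode = mode, stack = stack, min_loop = as.integer(min_loop)),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> mode=%s, min_loop=%d\n", x$mode, x$min_loop))
  invisible(x)
}

#' Fold a sequence to its minimum-energy nested structure
#'
#' Computes the nested structure minimizing the model energy over allowed
#' pairs with the model's minimum hairpin loop. Ties are resolved
#' deterministically: lowest energy, then fewest pairs, then a fixed
#' traceback preference.
#'
#' @param residues residue string (normalized internally).
#' @param model an [energy_model()].
#' @return list with `structure` (an [arc_annotated()]) and `mfe` (model
#'   units; `<= 0`, the empty structure scoring 0).
#' @export
#' @examples
#' fold_mfe("GGGAAAACCC", energy_model("bp"))
fold_mfe <- function(residues, model = energy_model("bp")) {
  stopifnot(inherits(model, "energy_model"))
  res <- normalize_rna(residues)
  if (nchar(res) == 0L)
    return(list(structure = arc_annotated(""), mfe = 0))
  out <- .cpp_fold(res_to_int(res), if (model$mode == "bp") 0L else 1L,
                   model$stack, model$min_loop)
  list(structure = arc_annotated(res, out$arcs), mfe = out$mfe)
}

# score an existing nested structure under a model (self-consistency checks)
rescore_structure <- function(x, model) {
  stopifnot(inherits(x, "arc_annotated"), x$nested)
  arcs <- x$arcs
  if (NROW(arcs) == 0L) return(0)
  if (model$mode == "bp") return(-NROW(arcs))
  bases <- strsplit(x$residues, "", fixed = TRUE)[[1]]
  pt <- function(i, j) paste0(bases[i], bases[j])
  e <- 0
  key <- paste(arcs[, 1], arcs[, 2])
  inner <- paste(arcs[, 1] + 1L, arcs[, 2] - 1L)
  stacked <- inner %in% key
  for (a in which(stacked)) {
    e <- e + model$stack[pt(arcs[a, 1], arcs[a, 2]),
                         pt(arcs[a, 1] + 1L, arcs[a, 2] - 1L)]
  }
  e
}

#' Scan a sequence for locally stable structures
#'
#' Folds every window of length `min(L, sequence length)` starting at
#' `1, 1+step, 1+2*step, ...` (a final window is added so the tail is always
#' covered), trims each window's structure to its outermost-arc extent, and
#' deduplicates candidates whose trimmed intervals overlap by more than 50%
#' of the shorter interval, keeping the lower energy (ties: earlier start).
#' Windows folding to the empty structure are suppressed.
#'
#' @param record a [seq_record()] (or residue string).
#' @param L maximum candidate span (fold window length), `>= 20`.
#' @param step window step, `1 <= step <= L`.
#' @param model an [energy_model()].
#' @return list of local candidates, each a list with `start`, `end` (1-based
#'   inclusive on the parent sequence), `slen`, `structure` (trimmed,
#'   re-indexed to the candidate interval) and `mfe`; sorted by `start`.
#' @export
scan_local <- function(record, L = 250L, step = 50L,
                       model = energy_model("bp")) {
  if (is.character(record)) record <- seq_record("seq1", record)
  stopifnot(inherits(record, "seq_record"))
  L <- as.integer(L); step <- as.integer(step)
  if (L < 20L) stop("L must be >= 20", call. = FALSE)
  if (step < 1L || step > L) stop("step must be in [1, L]", call. = FALSE)
  n <- record$length
  if (n == 0L) return(list())
  w <- min(L, n)
  starts <- seq.int(1L, max(1L, n - w + 1L), by = step)
  if (starts[length(starts)] + w - 1L < n) starts <- c(starts, n - w + 1L)
  cands <- list()
  for (s in starts) {
    sub <- substr(record$residues, s, s + w - 1L)
    f <- fold_mfe(sub, model)
    arcs <- f$structure$arcs
    if (NROW(arcs) == 0L) next
    lo <- min(arcs[, 1]); hi <- max(arcs[, 2])
    cands[[length(cands) + 1L]] <- list(
      start = s + lo - 1L, end = s + hi - 1L, slen = hi - lo + 1L,
      structure = arc_annotated(substr(sub, lo, hi),
                                cbind(arcs[, 1] - lo + 1L, arcs[, 2] - lo + 1L)),
      mfe = f$mfe)
  }
  if (length(cands) == 0L) return(list())
  # dedup: visit by (energy, start), keep unless >50% overlap with a kept one
  ord <- order(vapply(cands, `[[`, numeric(1), "mfe"),
               vapply(cands, `[[`, integer(1), "start"))
  kept <- list()
  for (k in ord) {
    ck <- cands[[k]]
    clash <- FALSE
    for (g in kept) {
      ov <- min(ck$end, g$end) - max(ck$start, g$start) + 1L
      if (ov > 0.5 * min(ck$slen, g$slen)) { clash <- TRUE; break }
    }
    if (!clash) kept[[length(kept) + 1L]] <- ck
  }
  kept[order(vapply(kept, `[[`, integer(1), "start"))]
}
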