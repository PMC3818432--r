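#' @useDynLib iresscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef predict runif setNames var
"_PACKAGE"

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Normalize a raw RNA/DNA string
#'
#' Uppercases, maps T to U, strips whitespace and digits (so numbered,
#' line-wrapped sequence blocks paste cleanly). Any residue outside
#' `A, C, G, U, T, N` (either case) is an error naming the offending
#' character and its position in the raw input.
#'
#' @param raw character scalar of raw sequence text.
#' @return normalized residue string over `{A,C,G,U,N}`.
#' @export
#' @examples
#' normalize_rna("acgt")        # "ACGU"
#' normalize_rna("AC GU\n1 AC") # "ACGUAC"
normalize_rna <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  keep <- !grepl("[[:space:][:digit:]]", chars)
  kept <- toupper(chars[keep])
  kept[kept == "T"] <- "U"
  bad <- which(!(kept %in% RNA_ALPHABET))
  if (length(bad) > 0L) {
    pos_raw <- which(keep)[bad[1L]]
    stop(sprintf("invalid residue '%s' at position %d", chars[pos_raw], pos_raw),
         call. = FALSE)
  }
  paste(kept, collapse = "")
}

#' Construct a sequence record
#'
#' @param id record identifier (FASTA header token).
#' @param residues residue string; normalized via [normalize_rna()].
#' @param description free-text description.
#' @return an object of class `seq_record` with fields `id`, `description`,
#'   `residues`, `length`.
#' @export
seq_record <- function(id, residues, description = "") {
  res <- normalize_rna(residues)
  structure(list(id = as.character(id), description = as.character(description),
                 residues = res, length = nchar(res)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d nt)%s\n", x$id, x$length,
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Read FASTA or plain sequence text
#'
#' Multi-record FASTA is parsed in file order; line-wrapped sequences are
#' joined. Input with no `>` header lines is accepted as a single anonymous
#' record with id `"seq1"`. Sequence text appearing before the first header
#' of a FASTA file is an error naming the line.
#'
#' @param source path to a file, or a character vector of lines / a single
#'   string containing the text itself.
#' @return list of [seq_record()] objects (empty list for empty input).
#' @export
read_fasta <- function(source) {
  stopifnot(is.character(source))
  if (length(source) == 1L && !grepl("[\n>]", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(list())
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    return(list(seq_record("seq1", paste(lines, collapse = ""))))
  }
  before <- nonempty[nonempty < headers[1L]]
  if (length(before) > 0L) {
    stop(sprintf("sequence text before first FASTA header at line %d",
                 before[1L]), call. = FALSE)
  }
  records <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    header <- sub("^>\\s*", "", lines[headers[k]])
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id)) id <- sprintf("seq%d", k)
    desc <- trimws(sub("^\\S+", "", trimws(header)))
    if (bounds[k + 1L] - 1L < headers[k] + 1L) {
      body <- character(0)
    } else {
      body <- lines[seq.int(headers[k] + 1L, bounds[k + 1L] - 1L)]
    }
    records[[k]] <- seq_record(id, paste(body, collapse = ""), desc)
  }
  records
}

#' Construct an arc-annotated sequence
#'
#' A residue string plus a set of base-pair arcs. Each position may sit in at
#' most one arc; every arc must span at least `min_loop + 1 = 4` positions
#' (three unpaired bases in a hairpin loop). `nested` records whether no two
#' arcs cross; folding output is always nested, pseudoknot output is not.
#'
#' @param residues residue string (normalized via [normalize_rna()]).
#' @param arcs integer matrix with two columns `(i, j)`, `1 <= i < j <= length`;
#'   0-row matrix or `NULL` for an unstructured sequence.
#' @return object of class `arc_annotated` with fields `residues`, `arcs`
#'   (matrix sorted by `i`), `length`, `nested`.
#' @export
arc_annotated <- function(residues, arcs = NULL) {
  res <- normalize_rna(residues)
  n <- nchar(res)
  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- matrix(integer(0), ncol = 2)
  } else {
    arcs <- matrix(as.integer(arcs), ncol = 2)
  }
  if (NROW(arcs) > 0L) {
    if (any(arcs[, 1] < 1L | arcs[, 2] > n | arcs[, 1] >= arcs[, 2]))
      stop("arcs must satisfy 1 <= i < j <= length", call. = FALSE)
    if (any(arcs[, 2] - arcs[, 1] < 4L))
      stop("every arc must span at least 4 positions (hairpin loop >= 3)",
           call. = FALSE)
    idx <- as.vector(arcs)
    if (anyDuplicated(idx) > 0L)
      stop("each position may participate in at most one arc", call. = FALSE)
    arcs <- arcs[order(arcs[, 1]), , drop = FALSE]
  }
  colnames(arcs) <- c("i", "j")
  structure(list(residues = res, arcs = arcs, length = n,
                 nested = !arcs_cross(arcs)),
            class = "arc_annotated")
}

# TRUE if any two arcs cross (i < k < j < l)
arcs_cross <- function(arcs) {
  na <- NROW(arcs)
  if (na < 2L) return(FALSE)
  for (a in seq_len(na - 1L)) {
    i <- arcs[a, 1]; j <- arcs[a, 2]
    k <- arcs[(a + 1L):na, 1]; l <- arcs[(a + 1L):na, 2]
    if (any((i < k & k < j & j < l) | (k < i & i < l & l < j))) return(TRUE)
  }
  FALSE
}

#' @export
print.arc_annotated <- function(x, ...) {
  cat(sprintf("<arc_annotated> %d nt, %d arcs%s\n", x$length, NROW(x$arcs),
              if (x$nested) ", nested" else ", crossing"))
  if (x$length <= 120) {
    cat(x$residues, "\n", sep = "")
    cat(write_dotbracket(x), "\n", sep = "")
  }
  invisible(x)
}

#' Parse a dot-bracket structure string
#'
#' Round brackets give the primary (nested) arc layer; square brackets give a
#' second layer that may cross the first (used for pseudoknotted structures).
#'
#' @param db dot-bracket string over `. ( ) [ ]`, same length as `residues`.
#' @param residues residue string.
#' @return an [arc_annotated()] object.
#' @export
#' @examples
#' parse_dotbracket("((...))", "GGAAACC")
parse_dotbracket <- function(db, residues) {
  res <- normalize_rna(residues)
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  if (length(chars) != nchar(res))
    stop("dot-bracket length does not match sequence length", call. = FALSE)
  ok <- chars %in% c(".", "(", ")", "[", "]")
  if (!all(ok))
    stop(sprintf("invalid dot-bracket character '%s'", chars[!ok][1L]),
         call. = FALSE)
  arcs <- matrix(integer(0), ncol = 2)
  for (br in list(c("(", ")"), c("[", "]"))) {
    stack <- integer(0)
    for (pos in seq_along(chars)) {
      if (chars[pos] == br[1]) {
        stack <- c(stack, pos)
      } else if (chars[pos] == br[2]) {
        if (length(stack) == 0L)
          stop(sprintf("unbalanced '%s' at position %d", br[2], pos),
               call. = FALSE)
        arcs <- rbind(arcs, c(stack[length(stack)], pos))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L)
      stop(sprintf("unbalanced '%s' at position %d", br[1], stack[1L]),
           call. = FALSE)
  }
  arc_annotated(res, arcs)
}

#' Write a dot-bracket string
#'
#' The arcs are split into at most two mutually nested layers; the first is
#' written with round brackets, the second (crossing) layer with square
#' brackets. More than two crossing layers is an error.
#'
#' @param x an [arc_annotated()] object.
#' @return dot-bracket string.
#' @export
write_dotbracket <- function(x) {
  stopifnot(inherits(x, "arc_annotated"))
  out <- rep(".", x$length)
  arcs <- x$arcs
  if (NROW(arcs) == 0L) return(paste(out, collapse = ""))
  layer <- integer(NROW(arcs))
  for (a in seq_len(NROW(arcs))) {
    for (lay in 1:2) {
      prev <- which(layer == lay)
      clash <- FALSE
      if (length(prev) > 0L) {
        i <- arcs[a, 1]; j <- arcs[a, 2]
        k <- arcs[prev, 1]; l <- arcs[prev, 2]
        clash <- any((i < k & k < j & j < l) | (k < i & i < l & l < j))
      }
      if (!clash) { layer[a] <- lay; break }
    }
    if (layer[a] == 0L)
      stop("structure needs more than two bracket layers", call. = FALSE)
  }
  br <- list(c("(", ")"), c("[", "]"))
  for (a in seq_len(NROW(arcs))) {
    out[arcs[a, 1]] <- br[[layer[a]]][1]
    out[arcs[a, 2]] <- br[[layer[a]]][2]
  }
  paste(out, collapse = "")
}

#' Write a structure in CT (connect) format
#'
#' Standard CT layout: a header line with the length and title, then one line
#' per residue with index, base, previous index, next index, pairing partner
#' (0 if unpaired) and the index again.
#'
#' @param x an [arc_annotated()] object.
#' @param title title for the header line.
#' @return a single string of CT text (lines joined with `\n`).
#' @export
write_ct <- function(x, title = "structure") {
  stopifnot(inherits(x, "arc_annotated"))
  partner <- integer(x$length)
  if (NROW(x$arcs) > 0L) {
    partner[x$arcs[, 1]] <- x$arcs[, 2]
    partner[x$arcs[, 2]] <- x$arcs[, 1]
  }
  bases <- strsplit(x$residues, "", fixed = TRUE)[[1]]
  lines <- c(sprintf("%d %s", x$length, title),
             sprintf("%d %s %d %d %d %d", seq_len(x$length), bases,
                     seq_len(x$length) - 1L, seq_len(x$length) + 1L,
                     partner, seq_len(x$length)))
  paste(lines, collapse = "\n")
}

#' Read a CT (connect) format structure
#'
#' @param text CT text (single string or character vector of lines).
#' @return an [arc_annotated()] object.
#' @export
read_ct <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty CT input", call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n) || length(lines) - 1L < n)
    stop("malformed CT header or truncated body", call. = FALSE)
  bases <- character(n)
  partner <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]]
    if (length(f) < 6L) stop(sprintf("malformed CT line %d", k + 1L), call. = FALSE)
    bases[k] <- f[2]
    partner[k] <- as.integer(f[5])
  }
  arcs <- cbind(which(partner > seq_len(n)), partner[partner > seq_len(n)])
  arc_annotated(paste(bases, collapse = ""), arcs)
}
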