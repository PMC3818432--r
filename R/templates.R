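# run body with a private RNG stream, restoring the caller's state
with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  body()
}

# dot-bracket composition helpers for the synthetic group templates
db_hp <- function(stem, loop) {
  paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
}
db_stem <- function(stem, ...) {
  paste0(strrep("(", stem), paste0(...), strrep(")", stem))
}

# group-like synthetic architectures (150-250 nt):
# 1 CrPV-like  — compact intergenic-region layout: two stacked multibranch
#               domains plus a free-standing hairpin
# 2 HCV-like   — one long basal helix enclosing a multibranch (domain-III
#               flavour) plus a separate hairpin
# 3 EMCV-like  — large branched domain with long interior helices
# 4 PV-like    — series of separate stem-loop domains
template_dotbracket <- function(group_id) {
  switch(group_id,
    paste0("..",
           db_stem(12, "..", db_hp(9, 4), "..", db_hp(9, 4), ".."), "..",
           db_stem(10, "..", db_hp(10, 4), "..", db_hp(8, 4), ".."),
           "..", db_hp(12, 5), ".."),
    paste0("..",
           db_stem(14, "..", db_hp(10, 4), "..",
                   db_stem(9, "..", db_hp(8, 4), "..", db_hp(8, 4), ".."),
                   "..", db_hp(10, 4), "..", db_hp(8, 4), ".."),
           "..", db_hp(9, 4), ".."),
    paste0("...",
           db_stem(12, "..", db_hp(11, 4), "..",
                   db_stem(10, "..", db_hp(9, 4), ".."), "..",
                   db_hp(10, 5), ".."),
           "..", db_hp(13, 4), "..", db_hp(8, 4), ".."),
    paste0("..", db_hp(12, 4), "..",
           db_stem(10, "..", db_hp(9, 4), "..", db_hp(9, 4), ".."),
           "..", db_hp(10, 4), "..", db_hp(8, 4), ".."))
}

TEMPLATE_META <- data.frame(
  group_id = 1:4,
  name = c("CrPV", "HCV", "EMCV", "PV"),
  accession = c("AF218039", "AF177037", "X74312.1", "V01148.1"),
  file = c("group1_crpv_like_synthetic.txt", "group2_hcv_like_synthetic.txt",
           "group3_emcv_like_synthetic.txt", "group4_pv_like_synthetic.txt"),
  stringsAsFactors = FALSE)

# draw a sequence realizing a structure: arcs get Watson-Crick pairs with a
# 10% GU fraction, unpaired positions are uniform over A/C/G/U. Stem pairs
# are GC-biased (70% G:C), as in the thermodynamically stable conserved
# helices of real IRES domains; this is what makes a planted element the
# locally most stable structure against a uniform-random background.
realize_sequence <- function(db) {
  x <- parse_dotbracket(db, strrep("N", nchar(db)))
  bases <- sample(c("A", "C", "G", "U"), nchar(db), replace = TRUE)
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  if (NROW(x$arcs) > 0L) {
    for (a in seq_len(NROW(x$arcs))) {
      i <- x$arcs[a, 1]; j <- x$arcs[a, 2]
      if (runif(1) < 0.10) {
        gu <- if (runif(1) < 0.5) c("G", "U") else c("U", "G")
        bases[i] <- gu[1]; bases[j] <- gu[2]
      } else {
        bases[i] <- sample(c("A", "U", "G", "C"), 1,
                           prob = c(0.15, 0.15, 0.35, 0.35))
        bases[j] <- wc[[bases[i]]]
      }
    }
  }
  paste(bases, collapse = "")
}

#' Write the four synthetic group templates
#'
#' Generates the packaged synthetic stand-ins for the four IRES group
#' standards (CrPV-, HCV-, EMCV-, PV-like architectures, 150-250 nt) into
#' plain-text template files. Deterministic per seed. The accession strings
#' of the real standards are carried as opaque metadata only; the sequences
#' are synthetic realizations of group-like arc architectures, not the
#' database entries.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return invisibly, the paths written.
#' @export
write_synthetic_templates <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  with_seed(seed, function() {
    for (g in 1:4) {
      db <- template_dotbracket(g)
      seqn <- realize_sequence(db)
      meta <- TEMPLATE_META[g, ]
      path <- file.path(dir, meta$file)
      writeLines(c(
        "# synthetic IRES group template (generated stand-in, not a database entry)",
        paste0("group: ", g),
        paste0("name: ", meta$name),
        paste0("accession: ", meta$accession),
        paste0("cutoff_r: ", format(DEFAULT_CUTOFFS[g], nsmall = 2)),
        paste0("sequence: ", seqn),
        paste0("structure: ", db)), path)
      paths <<- c(paths, path)
    }
  })
  invisible(paths)
}

parse_template_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([a-z_]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop(sprintf("malformed template file '%s' (line %d)", path, which(bad)[1L]),
         call. = FALSE)
  vals <- vapply(kv, `[`, character(1), 3L)
  names(vals) <- vapply(kv, `[`, character(1), 2L)
  need <- c("group", "name", "sequence", "structure")
  miss <- setdiff(need, names(vals))
  if (length(miss) > 0L)
    stop(sprintf("template file '%s' missing field '%s'", path, miss[1L]),
         call. = FALSE)
  template <- tryCatch(
    parse_dotbracket(vals[["structure"]], vals[["sequence"]]),
    error = function(e) stop(sprintf("template file '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (!template$nested)
    stop(sprintf("template file '%s': template structure must be nested", path),
         call. = FALSE)
  cutoff <- if ("cutoff_r" %in% names(vals)) as.numeric(vals[["cutoff_r"]]) else NULL
  group_model(as.integer(vals[["group"]]), vals[["name"]], template,
              cutoff_r = cutoff,
              accession = if ("accession" %in% names(vals))
                vals[["accession"]] else NA_character_)
}

#' Load IRES group templates from a directory
#'
#' Reads one template file per group (`*.txt`, key/value lines with the
#' group's sequence and dot-bracket structure) and builds [group_model()]s
#' with the frozen default cut-offs (1.61, 1.98, 1.87, 1.58) unless the file
#' overrides them. A group with no file is skipped with a warning; a
#' malformed file is an error naming the file.
#'
#' @param dir template directory; `NULL` for the packaged synthetic templates.
#' @return list of [group_model()]s sorted by group id.
#' @export
load_templates <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "templates", package = "iresscan",
                       mustWork = TRUE)
  }
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  models <- lapply(sort(files), parse_template_file)
  ids <- vapply(models, `[[`, integer(1), "group_id")
  if (anyDuplicated(ids) > 0L)
    stop("duplicate group id across template files", call. = FALSE)
  missing <- setdiff(1:4, ids)
  if (length(missing) > 0L)
    warning(sprintf("no template for group(s) %s; skipping",
                    paste(missing, collapse = ", ")), call. = FALSE)
  models[order(ids)]
}
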