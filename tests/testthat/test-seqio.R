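test_that("normalize_rna uppercases, maps T to U and strips layout characters", {
  expect_identical(normalize_rna("acgt"), "ACGU")
  expect_identical(normalize_rna("AC GU\n1 AC"), "ACGUAC")
  expect_identical(normalize_rna(""), "")
  expect_identical(normalize_rna("NnT"), "NNU")
  expect_error(normalize_rna("ACXU"), "position 3")
  expect_error(normalize_rna("AC-GU"), "'-'")
})

test_that("read_fasta parses records in order and normalizes residues", {
  recs <- read_fasta(">s1\nACGT")
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$id, "s1")
  expect_identical(recs[[1]]$residues, "ACGU")
  expect_identical(recs[[1]]$length, 4L)

  recs <- read_fasta(">a\nAC\n>b\nGGU")
  expect_length(recs, 2L)
  expect_identical(vapply(recs, `[[`, character(1), "id"), c("a", "b"))
  expect_identical(vapply(recs, `[[`, integer(1), "length"), c(2L, 3L))

  expect_identical(read_fasta(""), list())

  # plain text: one anonymous record
  recs <- read_fasta("ACG\nUUA")
  expect_identical(recs[[1]]$id, "seq1")
  expect_identical(recs[[1]]$residues, "ACGUUA")

  # wrapped lines and descriptions
  recs <- read_fasta(">x some description here\nACGU\nACGU")
  expect_identical(recs[[1]]$description, "some description here")
  expect_identical(recs[[1]]$length, 8L)

  expect_error(read_fasta("ACGU\n>late\nACGU"), "line 1")
})

test_that("read_fasta output always satisfies the record invariants", {
  set.seed(401)
  for (k in 1:20) {
    n <- sample(1:40, 1)
    txt <- paste0(">r", k, "\n", tolower(random_rna(n)))
    rec <- read_fasta(txt)[[1]]
    expect_identical(rec$length, nchar(rec$residues))
    expect_true(grepl("^[ACGUN]*$", rec$residues))
  }
})

test_that("parse_dotbracket matches brackets by stack and layers by bracket type", {
  x <- parse_dotbracket("((...))", "GGAAACC")
  expect_equal(unname(x$arcs), rbind(c(1L, 7L), c(2L, 6L)))
  expect_true(x$nested)

  x <- parse_dotbracket(".......", "AAAAAAA")
  expect_identical(NROW(x$arcs), 0L)

  x <- parse_dotbracket("((..[[..))..]]", "GGAAGGAACCAACC")
  expect_false(x$nested)
  expect_identical(NROW(x$arcs), 4L)

  expect_error(parse_dotbracket("((...)", "GGAAAC"), "unbalanced")
  expect_error(parse_dotbracket("(....))", "GGAAACC"), "unbalanced")
  expect_error(parse_dotbracket("(...)", "GGAAAC"), "length")
})

test_that("arc_annotated enforces span, uniqueness and bounds invariants", {
  expect_error(arc_annotated("ACGUA", rbind(c(1, 4))), "span")
  expect_error(arc_annotated("ACGUACGUACGU", rbind(c(1, 6), c(6, 12))),
               "at most one arc")
  expect_error(arc_annotated("ACGUA", rbind(c(0, 5))), "1 <= i < j")
  x <- arc_annotated("GGAAACC", rbind(c(2, 6), c(1, 7)))
  expect_true(x$nested)
  # arcs are sorted by left endpoint
  expect_equal(x$arcs[, "i"], c(1L, 2L))
})

test_that("dot-bracket writer inverts the parser on one- and two-layer structures", {
  set.seed(402)
  for (k in 1:25) {
    x <- random_nested(sample(8:40, 1))
    y <- parse_dotbracket(write_dotbracket(x), x$residues)
    expect_identical(y$arcs, x$arcs)
  }
  # crossing layer round-trip
  db <- "((((...[[[.))))....]]]"
  x <- parse_dotbracket(db, strrep("A", nchar(db)))
  expect_identical(write_dotbracket(x), db)
})

test_that("CT output follows the connect layout and round-trips the arc set", {
  ct <- write_ct(parse_dotbracket("((...))", "GGAAACC"), "hairpin")
  lines <- strsplit(ct, "\n")[[1]]
  expect_length(lines, 8L)
  expect_match(lines[1], "^7 hairpin$")
  expect_identical(strsplit(lines[2], " ")[[1]],
                   c("1", "G", "0", "2", "7", "1"))

  ct <- write_ct(arc_annotated("AAA"), "unpaired")
  partners <- vapply(strsplit(strsplit(ct, "\n")[[1]][-1], " "),
                     `[`, character(1), 5L)
  expect_identical(partners, c("0", "0", "0"))

  set.seed(403)
  for (k in 1:50) {
    x <- random_nested(sample(6:50, 1))
    y <- read_ct(write_ct(x, "roundtrip"))
    expect_identical(y$arcs, x$arcs)
    expect_identical(y$residues, x$residues)
  }
})
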