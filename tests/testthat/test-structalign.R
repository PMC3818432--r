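test_that("edit cost constructor validates the cost family", {
  costs <- edit_costs()
  expect_equal(costs$base_deletion, 1.0)
  expect_equal(costs$arc_altering, 1.5)
  expect_error(edit_costs(base_mismatch = -1), "non-negative")
  # the altering cost is tied to breaking/removing by the endpoint
  # decomposition the aligner uses
  expect_error(edit_costs(arc_altering = 2.0), "arc_altering")
  expect_silent(edit_costs(arc_breaking = 2, arc_removing = 4,
                           arc_altering = 3))
})

test_that("identical structures align at distance zero with full-length trace", {
  set.seed(501)
  for (k in 1:10) {
    x <- random_nested(sample(5:30, 1))
    res <- align_structures(x, x)
    expect_identical(res$dist, 0)
    expect_identical(res$alen, x$length)
  }
})

test_that("aligning against an empty structure deletes everything", {
  res <- align_structures(arc_annotated("AAAA"), arc_annotated(""))
  expect_identical(res$dist, 4)
  expect_identical(res$alen, 4L)
  # arcs pay arc_removing instead of two base deletions
  x <- parse_dotbracket("((...))", "GGAAACC")
  res <- align_structures(x, arc_annotated(""))
  expect_identical(res$dist, 2 * 2 + 3 * 1)  # two arcs removed, three bases
})

test_that("alignment equals the exhaustive oracle on small random pairs", {
  set.seed(502)
  for (k in 1:30) {
    a <- random_nested(sample(2:7, 1))
    b <- random_nested(sample(2:7, 1))
    d <- align_structures(a, b)$dist
    expect_equal(d, oracle_align(a, b), tolerance = 1e-9,
                 info = paste(a$residues, b$residues))
  }
})

test_that("alignment distance is symmetric and satisfies the zero law", {
  set.seed(503)
  for (k in 1:12) {
    a <- random_nested(sample(4:20, 1))
    b <- random_nested(sample(4:20, 1))
    d1 <- align_structures(a, b)$dist
    d2 <- align_structures(b, a)$dist
    expect_equal(d1, d2, tolerance = 1e-9)
  }
  x <- random_nested(15)
  expect_identical(align_structures(x, x)$dist, 0)
  expect_identical(r_score(align_structures(x, x)), Inf)
})

test_that("ALEN is bounded by max and sum of the input lengths", {
  set.seed(504)
  for (k in 1:12) {
    a <- random_nested(sample(2:25, 1))
    b <- random_nested(sample(2:25, 1))
    res <- align_structures(a, b)
    expect_gte(res$alen, max(a$length, b$length))
    expect_lte(res$alen, a$length + b$length)
    expect_identical(res$alen, NROW(res$columns))
    # trace is a monotone global alignment covering every position once
    ai <- res$columns[res$columns[, 1] > 0, 1]
    bj <- res$columns[res$columns[, 2] > 0, 2]
    expect_identical(as.integer(ai), seq_len(a$length))
    expect_identical(as.integer(bj), seq_len(b$length))
  }
})

test_that("breaking one arc raises the distance by a bounded amount", {
  # provable bound: at most arc_breaking + 2*base_mismatch (exactly
  # arc_breaking when the matched arc's end bases agreed)
  set.seed(505)
  costs <- edit_costs()
  for (k in 1:12) {
    a <- random_nested(sample(8:20, 1))
    if (NROW(a$arcs) == 0L) next
    b <- a
    drop <- sample.int(NROW(a$arcs), 1L)
    b$arcs <- a$arcs[-drop, , drop = FALSE]
    b <- arc_annotated(b$residues, b$arcs)
    d0 <- align_structures(a, a, costs)$dist
    d1 <- align_structures(a, b, costs)$dist
    expect_lte(d1, d0 + costs$arc_breaking + 2 * costs$base_mismatch)
    # self-alignment pairs identical arcs, so here the exact bound applies
    expect_lte(d1, costs$arc_breaking)
  }
})

test_that("crossing inputs are rejected", {
  pk <- parse_dotbracket("((..[[..))..]]", "GGAAGGAACCAACC")
  nested <- random_nested(8)
  expect_error(align_structures(pk, nested), "nested")
})

test_that("r_score is the ALEN/DIST ratio with an infinite perfect-match sentinel", {
  mk <- function(alen, dist) {
    structure(list(dist = dist, alen = alen,
                   columns = matrix(integer(0), ncol = 2)),
              class = "alignment_result")
  }
  expect_identical(r_score(mk(100L, 50)), 2)
  expect_identical(r_score(mk(250L, 0)), Inf)
  expect_equal(r_score(mk(187L, 77.9)), 2.4005, tolerance = 1e-4)
})
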