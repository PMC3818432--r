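# Independent brute-force oracles and random-instance generators.
# These deliberately avoid the package's DP algorithms: folding and
# pseudoknot oracles enumerate configurations directly from the definitions;
# the alignment oracle enumerates every global alignment.

RNA4 <- c("A", "C", "G", "U")

can_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

random_rna <- function(n) paste(sample(RNA4, n, replace = TRUE), collapse = "")

# --- folding oracle ---------------------------------------------------------

# all nested arc sets over positions i..j (arcs as 2-col matrices), min span 4
enumerate_nested <- function(bases, i, j) {
  if (j - i < 4L) return(list(matrix(integer(0), ncol = 2)))
  out <- list()
  # position i unpaired
  for (s in enumerate_nested(bases, i + 1L, j)) out[[length(out) + 1L]] <- s
  # position i paired with k
  for (k in seq.int(i + 4L, j)) {
    if (!can_pair(bases[i], bases[k])) next
    inner <- enumerate_nested(bases, i + 1L, k - 1L)
    outer <- enumerate_nested(bases, k + 1L, j)
    for (s1 in inner) for (s2 in outer) {
      out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
    }
  }
  out
}

# optimal (energy, npairs) for bp mode by exhaustive enumeration
oracle_fold_bp <- function(residues) {
  bases <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(bases)
  if (n == 0L) return(list(mfe = 0, npairs = 0L))
  structs <- enumerate_nested(bases, 1L, n)
  sizes <- vapply(structs, NROW, integer(1))
  best <- max(sizes)
  list(mfe = -best, npairs = best,
       n_opt = sum(sizes == best))
}

# --- random nested structures ----------------------------------------------

# random nested arc-annotated structure of length n: greedy random arcs
random_nested <- function(n, density = 0.35) {
  bases <- sample(RNA4, n, replace = TRUE)
  used <- rep(FALSE, n)
  arcs <- matrix(integer(0), ncol = 2)
  if (n >= 5L) {
    for (try in seq_len(max(1L, round(density * n)))) {
      i <- sample.int(n, 1L)
      jmax <- n
      if (NROW(arcs) > 0L) {
        # stay nested: j must not cross existing arcs
        for (a in seq_len(NROW(arcs))) {
          if (i < arcs[a, 1]) jmax <- min(jmax, arcs[a, 1] - 1L)
          if (i > arcs[a, 1] && i < arcs[a, 2]) jmax <- min(jmax, arcs[a, 2] - 1L)
        }
      }
      if (jmax < i + 4L) next
      js <- seq.int(i + 4L, jmax)
      j <- js[sample.int(length(js), 1L)]
      if (used[i] || used[j]) next
      # force complementarity so the arc is chemically plausible
      bases[j] <- c(A = "U", U = "A", G = "C", C = "G")[[bases[i]]]
      arcs <- rbind(arcs, c(i, j))
      used[c(i, j)] <- TRUE
    }
  }
  arc_annotated(paste(bases, collapse = ""), arcs)
}

# --- alignment oracle -------------------------------------------------------

# exhaustive minimum alignment cost between two nested arc-annotated
# structures under the six-operation model: enumerate every global alignment
# (monotone column sequence); arcs whose endpoint columns coincide may be
# arc-matched or both dissolved (minimum taken); dissolved arcs pay
# breaking/altering/removing by the fates of their endpoints.
oracle_align <- function(a, b, costs = list(del = 1, mis = 1, arcmis = 1,
                                            brk = 1, alter = 1.5, rem = 2)) {
  abase <- strsplit(a$residues, "", fixed = TRUE)[[1]]
  bbase <- strsplit(b$residues, "", fixed = TRUE)[[1]]
  n <- length(abase); m <- length(bbase)
  apart <- rep(0L, max(n, 1L)); bpart <- rep(0L, max(m, 1L))
  if (NROW(a$arcs) > 0L) {
    apart[a$arcs[, 1]] <- a$arcs[, 2]; apart[a$arcs[, 2]] <- a$arcs[, 1]
  }
  if (NROW(b$arcs) > 0L) {
    bpart[b$arcs[, 1]] <- b$arcs[, 2]; bpart[b$arcs[, 2]] <- b$arcs[, 1]
  }
  best <- Inf
  # partnerA[p] = aligned b-position or 0 (gap); same for B
  eval_alignment <- function(partnerA, partnerB) {
    cost <- 0
    # base columns not involving arc endpoints resolved later; first collect
    # which columns belong to a matched arc pair
    bc <- function(p, q) if (abase[p] == bbase[q]) 0 else costs$mis
    # candidate matched pairs: coinciding endpoints
    matched_a <- rep(FALSE, max(n, 1L)); matched_b <- rep(FALSE, max(m, 1L))
    if (NROW(a$arcs) > 0L) {
      for (aa in seq_len(NROW(a$arcs))) {
        p1 <- a$arcs[aa, 1]; p2 <- a$arcs[aa, 2]
        q1 <- partnerA[p1];  q2 <- partnerA[p2]
        if (q1 > 0L && q2 > 0L && bpart[q1] == q2 && q1 < q2) {
          # coinciding arc pair: min(arc match, both broken)
          arcsub <- if (abase[p1] == bbase[q1] && abase[p2] == bbase[q2] &&
                        abase[p1] != "N" && abase[p2] != "N") 0 else costs$arcmis
          both_broken <- 2 * costs$brk + bc(p1, q1) + bc(p2, q2)
          cost <- cost + min(arcsub, both_broken)
          matched_a[c(p1, p2)] <- TRUE
          matched_b[c(q1, q2)] <- TRUE
        }
      }
    }
    dissolved <- function(arcs, partner, matched) {
      extra <- 0
      if (NROW(arcs) > 0L) {
        for (aa in seq_len(NROW(arcs))) {
          p1 <- arcs[aa, 1]; p2 <- arcs[aa, 2]
          if (matched[p1]) next
          kept1 <- partner[p1] > 0L; kept2 <- partner[p2] > 0L
          extra <- extra + if (kept1 && kept2) costs$brk
                           else if (!kept1 && !kept2) costs$rem
                           else costs$alter
        }
      }
      extra
    }
    cost <- cost + dissolved(a$arcs, partnerA, matched_a)
    cost <- cost + dissolved(b$arcs, partnerB, matched_b)
    # per-column base costs (columns of matched arc pairs excluded; gapped
    # endpoints of dissolved arcs are covered by alter/remove)
    for (p in seq_len(n)) {
      q <- partnerA[p]
      if (q > 0L) {
        if (!matched_a[p]) cost <- cost + bc(p, q)
      } else if (apart[p] == 0L) {
        cost <- cost + costs$del
      }
    }
    for (q in seq_len(m)) {
      if (partnerB[q] == 0L && bpart[q] == 0L) cost <- cost + costs$del
    }
    cost
  }
  partnerA <- rep(0L, max(n, 1L)); partnerB <- rep(0L, max(m, 1L))
  recurse <- function(i, j) {
    if (i > n && j > m) {
      cost <- eval_alignment(partnerA, partnerB)
      if (cost < best) best <<- cost
      return(invisible(NULL))
    }
    if (i <= n) {                      # delete a[i]
      partnerA[i] <<- 0L; recurse(i + 1L, j)
    }
    if (j <= m) {                      # delete b[j]
      partnerB[j] <<- 0L; recurse(i, j + 1L)
    }
    if (i <= n && j <= m) {            # align a[i] with b[j]
      partnerA[i] <<- j; partnerB[j] <<- i
      recurse(i + 1L, j + 1L)
      partnerA[i] <<- 0L; partnerB[j] <<- 0L
    }
    invisible(NULL)
  }
  if (n == 0L && m == 0L) return(0)
  recurse(1L, 1L)
  best
}

# --- pseudoknot oracle ------------------------------------------------------

# exhaustive two-crossing-helix search: all anchor tuples and helix lengths,
# validity checked directly from the definitions
oracle_pknot <- function(residues, min_helix = 3L, min_loop = 3L) {
  bases <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(bases)
  best <- Inf
  valid_helix <- function(i, j, h) {
    for (t in 0:(h - 1)) {
      p <- i + t; q <- j - t
      if (q - p < min_loop + 1L) return(FALSE)
      if (!can_pair(bases[p], bases[q])) return(FALSE)
    }
    TRUE
  }
  if (n < 4L * min_helix + 2L) return(list(found = FALSE, energy = 0))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + min_loop + 1L, n)) {
      if (j > n || j <= i + min_loop) next
      for (k in seq.int(i + 1L, j - 1L)) {
        if (j + 1L > n) next
        for (l in seq.int(j + 1L, n)) {
          for (h1 in seq_len(floor((j - i) / 2))) {
            if (h1 < min_helix) next
            if (i + h1 - 1L >= k) break
            if (!valid_helix(i, j, h1)) break
            for (h2 in seq_len(floor((l - k) / 2))) {
              if (h2 < min_helix) next
              if (k + h2 - 1L > j - h1) break
              if (l - h2 + 1L <= j) break
              if (!valid_helix(k, l, h2)) break
              e <- -(h1 + h2)
              if (e < best) best <- e
            }
          }
        }
      }
    }
  }
  if (is.infinite(best)) list(found = FALSE, energy = 0)
  else list(found = TRUE, energy = as.numeric(best))
}

# --- misc -------------------------------------------------------------------

jaccard_interval <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  union <- max(a[2], b[2]) - min(a[1], b[1]) + 1
  inter / union
}
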