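# Independent oracles used to cross-check the folding, duplex, target-rule
# and count-test engines. These deliberately re-derive results by brute force
# (exhaustive enumeration / direct recounting), sharing only the published
# thermodynamic parameter values with the implementation under test.

oracle_env <- local({
  em <- mirpipe::energy_model()
  list(stack = em$stack, pars = em$params)
})

o_enc <- function(s) {
  m <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  unname(m[strsplit(chartr("tT", "UU", toupper(s)), "")[[1]]])
}

o_pair_idx <- function(x, y) {
  key <- paste0(c("A", "C", "G", "U")[x + 1], c("A", "C", "G", "U")[y + 1])
  idx <- c(AU = 1, UA = 2, CG = 3, GC = 4, GU = 5, UG = 6)[key]
  ifelse(is.na(idx), -1L, as.integer(idx))
}

o_hairpin <- function(n) {
  p <- oracle_env$pars
  if (n < p["min_hairpin"]) return(Inf)
  unname(p["hairpin_base"] + p["loop_log_coef"] * log(n / p["min_hairpin"]))
}
o_bulge <- function(n) {
  p <- oracle_env$pars
  unname(p["bulge_base"] + p["loop_log_coef"] * log(n))
}
o_internal <- function(n1, n2) {
  p <- oracle_env$pars
  unname(p["internal_base"] + p["loop_log_coef"] * log((n1 + n2) / 2) +
           min(p["asym_coef"] * abs(n1 - n2), p["asym_max"]))
}
o_interior <- function(g1, g2) {
  p <- oracle_env$pars
  if (g1 + g2 > p["max_loop"]) return(Inf)
  if (g1 == 0 || g2 == 0) o_bulge(g1 + g2) else o_internal(g1, g2)
}

# all pseudoknot-free structures (lists of pairs) of a coded sequence
enum_structures <- function(code, minhp = 3L) {
  n <- length(code)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1L, j)
    for (kk in (i + 1L):j) {
      if (kk > j || kk - i - 1L < minhp) next
      if (o_pair_idx(code[i], code[kk]) < 0) next
      inner <- rec(i + 1L, kk - 1L)
      outer <- rec(kk + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- c(list(c(i, kk)), a, b)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# energy of an explicit structure by loop decomposition
structure_energy <- function(code, prs) {
  if (length(prs) == 0) return(0)
  st <- oracle_env$stack
  pm <- do.call(rbind, prs)
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  pt <- integer(length(code))
  pt[pm[, 1]] <- pm[, 2]
  pt[pm[, 2]] <- pm[, 1]
  E <- 0
  p <- oracle_env$pars
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, 1]; j <- pm[r, 2]
    kids <- list(); k <- i + 1L
    while (k < j) {
      if (pt[k] > k) { kids[[length(kids) + 1L]] <- c(k, pt[k]); k <- pt[k] + 1L }
      else k <- k + 1L
    }
    if (length(kids) == 0) {
      E <- E + o_hairpin(j - i - 1L)
    } else if (length(kids) == 1) {
      kk <- kids[[1]]
      g1 <- kk[1] - i - 1L; g2 <- j - kk[2] - 1L
      if (g1 == 0 && g2 == 0)
        E <- E + st[o_pair_idx(code[i], code[j]),
                    o_pair_idx(code[kk[1]], code[kk[2]])]
      else E <- E + o_interior(g1, g2)
    } else {
      unp <- (j - i - 1L) -
        sum(vapply(kids, function(kk) kk[2] - kk[1] + 1L, 1L))
      E <- E + p["ml_a"] + p["ml_b"] * (1 + length(kids)) + p["ml_c"] * unp
    }
    if (!is.finite(E)) return(Inf)
  }
  unname(E)
}

# exhaustive MFE by enumeration
fold_oracle <- function(seq) {
  code <- o_enc(seq)
  structs <- enum_structures(code)
  min(c(0, vapply(structs, function(p) structure_energy(code, p), 0)))
}

# exact optimum over all monotone intermolecular pairings: memoised recursion
# anchored on the first pair (top-down; independent of the DP under test)
duplex_oracle <- function(a, b) {
  ca <- o_enc(a)
  cb <- rev(o_enc(b))
  n <- length(ca); m <- length(cb)
  st <- oracle_env$stack
  memo <- matrix(NA_real_, n, m)
  f <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- 0
    p <- o_pair_idx(ca[i], cb[j])
    if (i < n && j < m) {
      for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
        q <- o_pair_idx(ca[i2], cb[j2])
        if (q < 0) next
        g1 <- i2 - i - 1L; g2 <- j2 - j - 1L
        e <- if (g1 == 0 && g2 == 0) st[p, q] else o_interior(g1, g2)
        if (is.finite(e)) best <- min(best, e + f(i2, j2))
      }
    }
    memo[i, j] <<- best
    best
  }
  ans <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    if (o_pair_idx(ca[i], cb[j]) > 0) ans <- min(ans, f(i, j))
  ans
}

# exact two-sided conditional count test via R's binomial tails
count_pvalue_oracle <- function(x, y, n1, n2) {
  t <- x + y
  if (t == 0) return(1)
  q <- n2 / (n1 + n2)
  lower <- stats::pbinom(y, t, q)
  upper <- stats::pbinom(y - 1, t, q, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# independent target-rule evaluator: re-derives per-position status with
# string pasting and checks each rule with explicit loops
rules_oracle <- function(mirna, site, mfe_ratio, mfe_ratio_min = 0.75) {
  m <- strsplit(chartr("tT", "UU", toupper(mirna)), "")[[1]]
  s <- strsplit(chartr("tT", "UU", toupper(site)), "")[[1]]
  L <- length(m)
  status <- character(L)
  for (i in seq_len(L)) {
    b <- s[L - i + 1]
    pr <- paste0(m[i], b)
    status[i] <- if (pr %in% c("AU", "UA", "CG", "GC")) "match"
    else if (pr %in% c("GU", "UG")) "GU" else "mismatch"
  }
  wt <- function(ix) {
    tot <- 0
    for (i in ix) tot <- tot + switch(status[i], mismatch = 1, GU = 0.5, 0)
    tot
  }
  longest_mm_run <- 0
  run <- 0
  for (i in seq_len(L)) {
    run <- if (status[i] == "mismatch") run + 1 else 0
    longest_mm_run <- max(longest_mm_run, run)
  }
  adj_2_12 <- FALSE
  for (i in 2:11)
    if (status[i] == "mismatch" && status[i + 1] == "mismatch")
      adj_2_12 <- TRUE
  c(rule1 = wt(1:L) <= 4,
    rule2 = longest_mm_run <= 2,
    rule3 = !adj_2_12,
    rule4 = status[10] != "mismatch" && status[11] != "mismatch",
    rule5 = wt(1:12) <= 2.5,
    rule6 = isTRUE(mfe_ratio >= mfe_ratio_min))
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")
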