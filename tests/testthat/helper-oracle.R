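# Independent oracles: direct exhaustive enumeration of the two-locus
# pedigree likelihood, and plain re-scans for the filter operations.  These
# share no code with the package internals (explicit loops, own state
# encoding) so they can certify the peeling engine and set algebra.

# P(phenotype | number of disease alleles) by direct lookup
oracle_pen <- function(nD, phen, penetrance) {
  f <- penetrance[c(1, 2, 3)][c(3, 2, 1)[nD + 1]]  # nD=0 -> f_dd (3rd) etc.
  if (phen == "affected") f else if (phen == "unaffected") 1 - f else 1
}

# P(parent with ordered haplotypes (d1,m1),(d2,m2) transmits gamete (d,m))
oracle_trans <- function(pd1, pm1, pd2, pm2, d, m, theta) {
  pd <- c(pd1, pd2); pm <- c(pm1, pm2)
  p <- 0
  for (i in 1:2) for (j in 1:2) {
    if (pd[i] == d && pm[j] == m)
      p <- p + if (i == j) (1 - theta) / 2 else theta / 2
  }
  p
}

# per-individual enumeration of ordered two-locus states with nonzero
# penetrance x indicator x (prior); returns matrix (d1,m1,d2,m2) + weights
oracle_states <- function(row, call, model, marker, is_founder, eff_phen) {
  k <- marker$n_alleles
  q <- model$disease_allele_freq
  pen <- unname(model$penetrance)           # (f_DD, f_Dd, f_dd)
  grid <- expand.grid(d1 = 1:2, m1 = 1:k, d2 = 1:2, m2 = 1:k)
  w <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    nD <- (g$d1 == 1) + (g$d2 == 1)
    wi <- oracle_pen(nD, eff_phen, pen)
    if (!is.null(call)) {
      ok <- (g$m1 == call[1] && g$m2 == call[2]) ||
            (g$m1 == call[2] && g$m2 == call[1])
      if (!ok) wi <- 0
    }
    if (is_founder) {
      pd <- c(q, 1 - q)
      fr <- marker$allele_freqs
      wi <- wi * pd[g$d1] * fr[g$m1] * pd[g$d2] * fr[g$m2]
    }
    w[i] <- wi
  }
  keep <- w > 0
  list(states = as.matrix(grid[keep, , drop = FALSE]), w = w[keep])
}

# number of state combinations the exhaustive sum would visit
oracle_n_configs <- function(ped, gt, model) {
  m <- ped$members
  eff <- effective_phenotype(ped)
  calls <- gt$calls
  prod(vapply(seq_len(nrow(m)), function(i) {
    r <- calls[calls$id == m$id[i], ]
    call <- if (nrow(r) && !is.na(r$allele1[1])) c(r$allele1[1], r$allele2[1])
    st <- oracle_states(m[i, ], call, model, gt$marker,
                        is.na(m$father_id[i]), eff[[m$id[i]]])
    max(nrow(st$states), 1)
  }, numeric(1)))
}

# exhaustive-sum likelihood (linear scale); 0 for impossible data
oracle_likelihood <- function(ped, gt, model, theta, max_configs = 4e5) {
  m <- ped$members
  n <- nrow(m)
  eff <- effective_phenotype(ped)
  calls <- gt$calls
  per <- vector("list", n)
  for (i in seq_len(n)) {
    r <- calls[calls$id == m$id[i], ]
    call <- if (nrow(r) && !is.na(r$allele1[1])) c(r$allele1[1], r$allele2[1])
    per[[i]] <- oracle_states(m[i, ], call, model, gt$marker,
                              is.na(m$father_id[i]), eff[[m$id[i]]])
    if (nrow(per[[i]]$states) == 0) return(0)
  }
  counts <- vapply(per, function(p) nrow(p$states), integer(1))
  stopifnot(prod(counts) <= max_configs)
  idx_grid <- as.matrix(expand.grid(lapply(counts, seq_len)))
  total_w <- rep(1, nrow(idx_grid))
  for (i in seq_len(n)) total_w <- total_w * per[[i]]$w[idx_grid[, i]]
  # transmission factors: child hap1 from father, hap2 from mother
  fa_of <- match(m$father_id, m$id)
  mo_of <- match(m$mother_id, m$id)
  for (ch in which(!is.na(fa_of))) {
    fa <- fa_of[ch]; mo <- mo_of[ch]
    cs <- per[[ch]]$states; fs <- per[[fa]]$states; ms <- per[[mo]]$states
    Tfa <- matrix(0, nrow(cs), nrow(fs))
    Tmo <- matrix(0, nrow(cs), nrow(ms))
    for (a in seq_len(nrow(cs))) {
      for (b in seq_len(nrow(fs)))
        Tfa[a, b] <- oracle_trans(fs[b, "d1"], fs[b, "m1"], fs[b, "d2"],
                                  fs[b, "m2"], cs[a, "d1"], cs[a, "m1"], theta)
      for (b in seq_len(nrow(ms)))
        Tmo[a, b] <- oracle_trans(ms[b, "d1"], ms[b, "m1"], ms[b, "d2"],
                                  ms[b, "m2"], cs[a, "d2"], cs[a, "m2"], theta)
    }
    total_w <- total_w * Tfa[cbind(idx_grid[, ch], idx_grid[, fa])] *
      Tmo[cbind(idx_grid[, ch], idx_grid[, mo])]
  }
  sum(total_w)
}

# plain per-predicate QC re-scan (record loop, one predicate at a time)
oracle_qc_keep <- function(records, cfg) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ok <- TRUE
    if (r$quality < cfg$min_quality) ok <- FALSE
    if (r$copy_number >= cfg$copy_number_max_exclusive) ok <- FALSE
    if (r$var_type == "snv" && !is.na(r$nearest_snp_distance) &&
        r$nearest_snp_distance < cfg$min_adjacent_distance) ok <- FALSE
    if (r$depth < cfg$min_depth) ok <- FALSE
    if (r$depth > cfg$max_depth) ok <- FALSE
    keep[i] <- ok
  }
  keep
}

# brute-force transmission census for count_phase_known_meioses
oracle_meiosis_count <- function(ped, gt) {
  m <- ped$members
  calls <- gt$calls
  gcall <- function(id) {
    r <- calls[calls$id == id, ]
    if (!nrow(r) || is.na(r$allele1[1])) NULL else c(r$allele1[1], r$allele2[1])
  }
  n <- 0L
  for (i in seq_len(nrow(m))) {
    if (is.na(m$father_id[i])) next
    cg <- gcall(m$id[i])
    if (is.null(cg)) next
    fg <- gcall(m$father_id[i]); mg <- gcall(m$mother_id[i])
    fx <- character(0); mx <- character(0)
    for (perm in list(cg, rev(cg))) {
      okf <- is.null(fg) || perm[1] %in% fg
      okm <- is.null(mg) || perm[2] %in% mg
      if (okf && okm) { fx <- c(fx, perm[1]); mx <- c(mx, perm[2]) }
    }
    if (length(fx) && length(unique(fx)) == 1L) n <- n + 1L
    if (length(mx) && length(unique(mx)) == 1L) n <- n + 1L
  }
  n
}
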