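# Exact two-locus (disease x marker) pedigree likelihood by Elston-Stewart
# peeling over the nuclear-family tree.
#
# State space per individual: ordered pairs of haplotypes, one paternally and
# one maternally inherited.  A haplotype couples a disease allele d in {D, d}
# with a marker allele m in 1..k, so there are H = 2k haplotypes and
# S = H^2 ordered states.  Phase must be carried because recombination acts
# on haplotypes, not on unordered genotypes; the phase is summed out by the
# peeling itself.
#
# Founder priors assume linkage equilibrium: P(haplotype) = P(d) * P(m).
# A parent transmits a gamete by choosing, independently for the two loci,
# which of its two haplotypes contributes the allele; the choices agree with
# probability 1 - theta and disagree (a recombinant) with probability theta.

# haplotype index: h = (d - 1) * k + m, with d = 1 for D, d = 2 for normal
hap_components <- function(k) {
  H <- 2L * k
  list(H = H, S = H * H,
       d = rep(1:2, each = k),          # hap -> disease allele
       m = rep(seq_len(k), times = 2))  # hap -> marker allele
}

# state s = (h_pat - 1) * H + h_mat
state_haps <- function(H) {
  list(h1 = rep(seq_len(H), each = H),   # paternally inherited haplotype
       h2 = rep(seq_len(H), times = H))  # maternally inherited haplotype
}

# S x H gamete-transmission matrix: tau[s, h] = P(parent in state s transmits
# haplotype h).  Four contributions per state: disease allele from hap i,
# marker allele from hap j, weight (1-theta)/2 if i == j else theta/2.
tau_matrix <- function(theta, k) {
  hc <- hap_components(k)
  st <- state_haps(hc$H)
  S <- hc$S; H <- hc$H
  hap_of <- function(d, m) (d - 1L) * k + m
  tgt <- cbind(hap_of(hc$d[st$h1], hc$m[st$h1]),   # both from paternal hap
               hap_of(hc$d[st$h1], hc$m[st$h2]),   # disease pat, marker mat
               hap_of(hc$d[st$h2], hc$m[st$h2]),   # both from maternal hap
               hap_of(hc$d[st$h2], hc$m[st$h1]))   # disease mat, marker pat
  w <- c((1 - theta) / 2, theta / 2, (1 - theta) / 2, theta / 2)
  tau <- matrix(0, S, H)
  for (j in 1:4) {
    add <- matrix(0, S, H)
    add[cbind(seq_len(S), tgt[, j])] <- w[j]
    tau <- tau + add
  }
  tau
}

# per-individual state potentials: penetrance x marker-observation indicator
# x (founder prior if founder).  Returns an S x n matrix.
state_potentials <- function(ped, gt, model) {
  m <- ped$members
  k <- gt$marker$n_alleles
  hc <- hap_components(k)
  st <- state_haps(hc$H)
  nD <- (hc$d[st$h1] == 1L) + (hc$d[st$h2] == 1L)
  geno <- c("dd", "Dd", "DD")[nD + 1L]
  q <- model$disease_allele_freq
  pd <- c(q, 1 - q)
  pm <- gt$marker$allele_freqs
  hap_prob <- pd[hc$d] * pm[hc$m]
  prior <- hap_prob[st$h1] * hap_prob[st$h2]
  eff <- effective_phenotype(ped)
  calls <- gt$calls
  phi <- matrix(0, hc$S, nrow(m))
  m1 <- hc$m[st$h1]; m2 <- hc$m[st$h2]
  for (i in seq_len(nrow(m))) {
    v <- penetrance_prob(model, geno, eff[[m$id[i]]])
    r <- calls[calls$id == m$id[i], ]
    if (nrow(r) && !is.na(r$allele1[1])) {
      a <- r$allele1[1]; b <- r$allele2[1]
      v <- v * as.numeric((m1 == a & m2 == b) | (m1 == b & m2 == a))
    }
    if (is.na(m$father_id[i])) v <- v * prior
    phi[, i] <- v
  }
  phi
}

# message-passing over the bipartite (family x connector-individual) tree.
# Returns log10 likelihood, -Inf for data impossible under the model.
peel_loglik10 <- function(ped, gt, model, theta) {
  stopifnot(theta >= 0, theta <= 0.5)
  m <- ped$members
  k <- gt$marker$n_alleles
  hc <- hap_components(k)
  H <- hc$H; S <- hc$S
  phi <- state_potentials(ped, gt, model)
  nf <- nuclear_families(ped)
  fams <- nf$fams; ind2fams <- nf$ind2fams
  tau <- tau_matrix(theta, k)

  acc <- new.env(parent = emptyenv())
  acc$log10 <- 0
  acc$visited <- rep(FALSE, length(fams))
  zero_cond <- structure(class = c("lx_zero_lik", "condition"),
                         list(message = "zero", call = NULL))

  scale_vec <- function(v) {
    sc <- max(v)
    if (!is.finite(sc) || sc <= 0) stop(zero_cond)
    acc$log10 <- acc$log10 + log10(sc)
    v / sc
  }

  msg_ind <- function(i, from_fam) {
    v <- phi[, i]
    for (g in ind2fams[[i]]) if (g != from_fam) v <- v * msg_fam(g, i)
    v
  }

  # marginalise family f onto individual `to` (0 = root: return scalar total)
  msg_fam <- function(f, to) {
    acc$visited[f] <- TRUE
    fam <- fams[[f]]
    ct <- NULL
    for (ch in fam$kids) {
      if (ch == to) next
      psi <- scale_vec(msg_ind(ch, f))
      Pm <- matrix(psi, H, H, byrow = TRUE)      # Pm[h_pat, h_mat]
      term <- tau %*% Pm %*% t(tau)              # over (s_fa, s_mo)
      ct <- if (is.null(ct)) term else ct * term
    }
    if (to == fam$fa) {
      Wmo <- scale_vec(msg_ind(fam$mo, f))
      return(as.vector(ct %*% Wmo))
    }
    if (to == fam$mo) {
      Wfa <- scale_vec(msg_ind(fam$fa, f))
      return(as.vector(crossprod(ct, Wfa)))
    }
    Wfa <- scale_vec(msg_ind(fam$fa, f))
    Wmo <- scale_vec(msg_ind(fam$mo, f))
    if (to == 0L) {
      if (is.null(ct)) return(sum(Wfa) * sum(Wmo))   # unreachable: fams have kids
      return(as.numeric(t(Wfa) %*% ct %*% Wmo))
    }
    W <- outer(Wfa, Wmo)
    if (!is.null(ct)) W <- W * ct
    Mm <- crossprod(tau, W) %*% tau                  # Mm[h_pat, h_mat]
    as.vector(t(Mm))                                 # back to state order
  }

  res <- tryCatch({
    ll <- 0
    for (f in seq_along(fams)) {
      if (acc$visited[f]) next
      total <- msg_fam(f, 0L)
      if (total <= 0) stop(zero_cond)
      ll <- ll + log10(total)
    }
    isolated <- which(lengths(ind2fams) == 0L)
    for (i in isolated) {
      s <- sum(phi[, i])
      if (s <= 0) stop(zero_cond)
      ll <- ll + log10(s)
    }
    ll + acc$log10
  }, lx_zero_lik = function(e) -Inf)
  res
}

#' Two-locus pedigree likelihood
#'
#' Exact likelihood of the observed phenotypes and marker genotypes on a
#' loop-free pedigree, jointly over the disease locus and one marker, at
#' recombination fraction `theta`.  Computed by Elston-Stewart peeling over
#' ordered haplotype-pair states; see the package vignette for the model.
#' Mendelian-inconsistent genotype data give a likelihood of 0 (not an
#' error); pedigrees with marriage/consanguinity loops are rejected at
#' [pedigree()] construction.
#'
#' @param ped a [pedigree()].
#' @param gt a [genotype_table()] for one marker.
#' @param model a [disease_model()].
#' @param theta recombination fraction in `[0, 0.5]`.
#' @param log10 if `TRUE`, return the log10 likelihood (`-Inf` for
#'   impossible data) instead of the linear-scale value.
#' @return the likelihood (linear scale by default; the log10 value is also
#'   attached as attribute `"log10"`).
#' @export
two_locus_likelihood <- function(ped, gt, model, theta, log10 = FALSE) {
  ll <- peel_loglik10(ped, gt, model, theta)
  if (log10) return(ll)
  structure(10^ll, log10 = ll)
}
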