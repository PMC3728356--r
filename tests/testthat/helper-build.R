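# fixture builders used across test files

quick_ped <- function(ids, fathers, mothers, sexes, phens, flags = FALSE,
                      family_id = "T") {
  pedigree(data.frame(id = ids, father_id = fathers, mother_id = mothers,
                      sex = sexes, phenotype = phens,
                      below_onset_age = flags, stringsAsFactors = FALSE),
           family_id = family_id)
}

nuclear_ped <- function(n_kids = 3, phens = NULL) {
  ids <- c("fa", "mo", paste0("k", seq_len(n_kids)))
  quick_ped(ids,
            c(NA, NA, rep("fa", n_kids)),
            c(NA, NA, rep("mo", n_kids)),
            c("male", "female", rep(c("male", "female"), length.out = n_kids)),
            phens %||% rep("unknown", n_kids + 2))
}

empty_gt <- function(marker, ped = NULL) {
  genotype_table(marker, data.frame(id = character(0), allele1 = integer(0),
                                    allele2 = integer(0)), ped)
}

# random small pedigree + marker + model + genotypes, kept small enough for
# the exhaustive oracle; genotypes are gene-dropped (consistent) half the
# time and uniform-random (possibly Mendelian-inconsistent) otherwise
random_case <- function(max_configs = 3e5) {
  repeat {
    n_kids <- sample(2:4, 1)
    three_gen <- stats::runif(1) < 0.5
    ids <- c("fa", "mo", paste0("k", seq_len(n_kids)))
    fathers <- c(NA, NA, rep("fa", n_kids))
    mothers <- c(NA, NA, rep("mo", n_kids))
    sexes <- c("male", "female", rep(c("male", "female"), length.out = n_kids))
    if (three_gen) {
      n_g <- sample(1:2, 1)
      ids <- c(ids, "sp", paste0("g", seq_len(n_g)))
      k1_is_male <- sexes[3] == "male"
      fathers <- c(fathers, NA, rep(if (k1_is_male) "k1" else "sp", n_g))
      mothers <- c(mothers, NA, rep(if (k1_is_male) "sp" else "k1", n_g))
      sexes <- c(sexes, if (k1_is_male) "female" else "male",
                 rep("male", n_g))
    }
    n <- length(ids)
    phens <- sample(c("affected", "unaffected", "unknown"), n, replace = TRUE,
                    prob = c(0.3, 0.5, 0.2))
    flags <- stats::runif(n) < 0.1
    ped <- quick_ped(ids, fathers, mothers, sexes, phens, flags)
    k <- sample(2:3, 1)
    freqs <- if (stats::runif(1) < 0.5) NULL else {
      f <- stats::rgamma(k, 2); f / sum(f)
    }
    mk <- marker_locus("Mrand", "1", n_alleles = k, allele_freqs = freqs)
    model <- disease_model(sample(c(1e-4, 0.01, 0.1), 1),
                           c(0.9, 0.9, sample(c(0, 0.05), 1)))
    theta <- stats::runif(1, 0, 0.5)
    if (stats::runif(1) < 0.5) {
      gd <- gene_drop(ped, model, mk, theta)
      calls <- gd$genotypes$calls
    } else {
      calls <- data.frame(id = ids,
                          allele1 = sample(seq_len(k), n, replace = TRUE),
                          allele2 = sample(seq_len(k), n, replace = TRUE))
    }
    drop <- stats::runif(n) < 0.3
    calls$allele1[drop] <- NA; calls$allele2[drop] <- NA
    gt <- genotype_table(mk, calls, ped)
    if (oracle_n_configs(ped, gt, model) <= max_configs)
      return(list(ped = ped, gt = gt, model = model, theta = theta))
  }
}

# phase-known fully-penetrant pedigree whose LOD has the closed form
# m * log10(2) at theta = 0 for m non-recombinant meioses
analytic_ped_case <- function(m_meioses = 10) {
  n_aff <- ceiling(m_meioses / 2)
  n_un <- m_meioses - n_aff
  kid_phen <- c(rep("affected", n_aff), rep("unaffected", n_un))
  kids <- paste0("c", seq_len(m_meioses))
  ped <- quick_ped(c("gf", "gm", "fa", "mo", kids),
                   c(NA, NA, "gf", NA, rep("fa", m_meioses)),
                   c(NA, NA, "gm", NA, rep("mo", m_meioses)),
                   c("male", "female", "male", "female",
                     rep("male", m_meioses)),
                   c("affected", "unaffected", "affected", "unaffected",
                     kid_phen))
  mk <- marker_locus("Mk", "1", n_alleles = 3)
  calls <- data.frame(
    id = c("gf", "gm", "fa", "mo", kids),
    allele1 = c(1, 2, 1, 3, ifelse(kid_phen == "affected", 1, 2)),
    allele2 = c(1, 2, 2, 3, rep(3, m_meioses)))
  list(ped = ped, gt = genotype_table(mk, calls, ped),
       model = disease_model(1e-4, c(1, 1, 0)))
}

# run QC + cascade + co-segregation on one simulated exome dataset and
# report whether the planted variant is the recovered candidate
recover_planted <- function(sim) {
  kept <- lapply(sim$per_sample, function(tab) apply_qc(tab)$kept)
  control_kept <- apply_qc(sim$control)$kept
  res <- run_cascade(kept, sim$sets,
                     known_variant_set("control", control_kept),
                     dfna56_interval())
  hit <- sim$truth$key %in% variant_key(res$final)
  coseg <- cosegregation_check(f013_pedigree(), sim$carrier_status)
  hit && coseg$verdict == "cosegregates"
}
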