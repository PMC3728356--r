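# Forward simulation: gene dropping on pedigrees and synthetic exome tables.
# A single seeded pseudo-random stream drives each generator; draw order is
# fixed (founders in topological order, then children locus-by-locus), so a
# fixed seed reproduces outputs exactly.

#' Gene-drop simulation of linked genotypes and phenotypes
#'
#' Drops a disease locus and one linked marker down a pedigree: founder
#' haplotypes are drawn from linkage-equilibrium frequencies (disease allele
#' frequency from `model`, marker frequencies from `marker`), each
#' transmission picks a parental haplotype per locus with recombination
#' probability `theta` between the loci, and phenotypes are drawn from the
#' model's penetrances given the simulated disease genotypes.
#'
#' For a rare disease allele an unconditioned founder population almost
#' never segregates disease; `founder_carrier` forces one named founder to
#' be a Dd carrier, which is how an ascertained disease family is emulated.
#'
#' @param ped a [pedigree()]; its phenotypes are ignored (new ones are
#'   drawn) but its `below_onset_age` flags are kept.
#' @param model a [disease_model()].
#' @param marker a [marker_locus()].
#' @param theta true recombination fraction between disease locus and
#'   marker.
#' @param seed optional integer seed (sets the session RNG).
#' @param founder_carrier optional id of a founder forced to carry one copy
#'   of the disease allele.
#' @return list with `ped` (pedigree carrying the drawn phenotypes),
#'   `genotypes` (a [genotype_table()]), `disease_genotypes` (named
#'   `DD`/`Dd`/`dd` vector), `carriers` (named logical), `n_meioses` and
#'   `n_recombinant` (marker-vs-disease recombination counts over all
#'   transmissions).
#' @export
gene_drop <- function(ped, model, marker, theta, seed = NULL,
                      founder_carrier = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(model, "disease_model"),
            inherits(marker, "marker_locus"), theta >= 0, theta <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  m <- ped$members
  topo <- attr(m, "topo_order")
  q <- model$disease_allele_freq
  k <- marker$n_alleles
  # per-individual haplotypes: hap[[id]] = 2x2 matrix, rows = (paternal,
  # maternal) haplotype, cols = (disease allele in {1=D,2=d}, marker allele)
  hap <- list()
  n_meioses <- 0L; n_recomb <- 0L
  if (!is.null(founder_carrier) &&
      !founder_carrier %in% m$id[is.na(m$father_id)])
    stop_lx("lx_unknown_individual", "founder_carrier '%s' is not a founder",
            founder_carrier)
  for (id in topo) {
    r <- m[m$id == id, ]
    if (is.na(r$father_id)) {
      d <- sample(1:2, 2, replace = TRUE, prob = c(q, 1 - q))
      if (!is.null(founder_carrier) && id == founder_carrier) d <- c(1L, 2L)
      mk <- sample(seq_len(k), 2, replace = TRUE, prob = marker$allele_freqs)
      hap[[id]] <- cbind(d = d, m = mk)
    } else {
      gam <- function(parent) {
        ph <- hap[[parent]]
        o_d <- sample(1:2, 1)                       # grandparental origin, disease
        o_m <- if (stats::runif(1) < theta) 3L - o_d else o_d
        n_meioses <<- n_meioses + 1L
        if (o_m != o_d) n_recomb <<- n_recomb + 1L
        c(d = ph[o_d, "d"], m = ph[o_m, "m"])
      }
      hap[[id]] <- rbind(gam(r$father_id), gam(r$mother_id))
      colnames(hap[[id]]) <- c("d", "m")
    }
  }
  nD <- vapply(m$id, function(id) sum(hap[[id]][, "d"] == 1L), integer(1))
  geno <- setNames(c("dd", "Dd", "DD")[nD + 1L], m$id)
  p_aff <- penetrance_prob(model, geno, "affected")
  phen <- ifelse(stats::runif(length(p_aff)) < p_aff, "affected", "unaffected")
  ped2 <- ped
  ped2$members$phenotype <- unname(phen)
  attr(ped2$members, "topo_order") <- topo
  calls <- data.frame(
    id = m$id,
    allele1 = vapply(m$id, function(id) hap[[id]][1L, "m"], integer(1)),
    allele2 = vapply(m$id, function(id) hap[[id]][2L, "m"], integer(1)),
    stringsAsFactors = FALSE)
  list(ped = ped2,
       genotypes = genotype_table(marker, calls, ped2),
       disease_genotypes = geno,
       carriers = nD > 0L,
       n_meioses = n_meioses,
       n_recombinant = n_recomb)
}

#' @describeIn gene_drop `simulate()` method: `nsim` independent gene drops.
#' @param object,nsim,... standard [stats::simulate()] arguments; `...` is
#'   passed to `gene_drop()`.
#' @export
simulate.pedigree <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) gene_drop(object, ...))
}

#' Replace pedigree phenotypes
#'
#' @param ped a [pedigree()].
#' @param phenotypes named character vector (`affected`/`unaffected`/
#'   `unknown`) covering the ids to change.
#' @return the updated pedigree.
#' @export
set_phenotypes <- function(ped, phenotypes) {
  unknown <- setdiff(names(phenotypes), ped$members$id)
  if (length(unknown))
    stop_lx("lx_unknown_individual", "phenotype for non-member(s): %s",
            paste(unknown, collapse = ", "))
  i <- match(names(phenotypes), ped$members$id)
  topo <- attr(ped$members, "topo_order")
  ped$members$phenotype[i] <- unname(phenotypes)
  attr(ped$members, "topo_order") <- topo
  ped
}

#' Configuration for the synthetic exome generator
#'
#' Defaults emulate the scale and structure of a dominant-disease exome
#' study on three affected relatives plus one unaffected control: roughly
#' 18,000 background coding variants, of which each sample carries about
#' 75%, with hierarchical database membership (a variant is "known" with
#' probability 0.93 and known variants are members of each public set with
#' the listed probabilities), so each sample retains on the order of 7,000
#' functional variants before database subtraction and a few hundred after
#' -- the magnitudes a whole-exome pipeline reports.  QC fields follow
#' quality ~ round N(60, 20), depth ~ NegBin(mean 50) (echoing ~50-fold
#' mean coverage), copy number ~ 1 + Exp(mean 0.1), nearest-SNP distance ~
#' Exp(mean 500).  See the vignette for the rationale behind each choice.
#'
#' @param n_background number of background coding variants in the cohort.
#' @param affected_samples ids of the sequenced affected individuals.
#' @param control_sample id of the sequenced unaffected control.
#' @param p_known probability a background variant is in public databases.
#' @param set_membership named per-set membership probabilities given known.
#' @param carry_known,carry_novel probability a given sample carries a
#'   known / novel background variant.
#' @param planted_inside_interval plant the causal variant inside the
#'   linked interval (`TRUE`) or elsewhere on its chromosome (`FALSE`).
#' @param planted_cosegregating if `FALSE`, one affected member is made a
#'   noncarrier so the co-segregation check must fail.
#' @param interval the linked interval (default: the packaged DFNA56
#'   interval).
#' @param seed integer seed; fixed seed gives identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_background = 18000,
                       affected_samples = c("IV:5", "IV:17", "IV:31"),
                       control_sample = "IV:3",
                       p_known = 0.93,
                       set_membership = c(dbSNP132 = 0.97,
                                          `1000Genomes` = 0.60,
                                          HapMap = 0.55, YH = 0.45),
                       carry_known = 0.80, carry_novel = 0.35,
                       planted_inside_interval = TRUE,
                       planted_cosegregating = TRUE,
                       interval = NULL,
                       seed = 1L) {
  probs <- c(p_known, set_membership, carry_known, carry_novel)
  stopifnot(all(probs >= 0), all(probs <= 1), n_background >= 0)
  structure(list(n_background = n_background,
                 affected_samples = affected_samples,
                 control_sample = control_sample,
                 p_known = p_known, set_membership = set_membership,
                 carry_known = carry_known, carry_novel = carry_novel,
                 planted_inside_interval = planted_inside_interval,
                 planted_cosegregating = planted_cosegregating,
                 interval = interval %||% dfna56_interval(),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# approximate chromosome lengths (Mb) for placing background variants
chrom_lengths_mb <- c(247, 243, 199, 191, 181, 171, 159, 146, 140, 135,
                      134, 132, 114, 106, 100, 89, 79, 76, 64, 62, 47, 50)

sample_qc_fields <- function(n) {
  data.frame(
    quality = pmax(0, round(stats::rnorm(n, 60, 20))),
    depth = stats::rnbinom(n, size = 10, mu = 50),
    copy_number = 1 + stats::rexp(n, rate = 10),
    nearest_snp_distance = round(stats::rexp(n, rate = 1 / 500)))
}

qc_passes <- function(fields, cfg = qc_config()) {
  fields$quality >= cfg$min_quality &
    fields$copy_number < cfg$copy_number_max_exclusive &
    fields$nearest_snp_distance >= cfg$min_adjacent_distance &
    fields$depth >= cfg$min_depth & fields$depth <= cfg$max_depth
}

random_codon_change <- function() {
  bases <- c("A", "C", "G", "T")
  repeat {
    cod <- sample(bases, 3, replace = TRUE)
    pos <- sample(1:3, 1)
    alt <- sample(setdiff(bases, cod[pos]), 1)
    new <- cod; new[pos] <- alt
    # avoid creating a stop in the reference codon for tidy annotations
    if (!paste(cod, collapse = "") %in% c("TAA", "TAG", "TGA")) break
  }
  new[pos] <- tolower(new[pos])
  paste0(paste(cod, collapse = ""), "-", paste(new, collapse = ""))
}

#' Simulate per-sample exome variant tables with a planted causal variant
#'
#' Generates background coding variants with independently sampled QC
#' fields, functional classes, database membership and per-sample
#' genotypes, plus one planted causal variant that (by default) lies inside
#' the linked interval, is absent from every database and from the control,
#' and is carried heterozygously by every affected sample.  The planted
#' variant's QC fields are drawn conditional on passing [apply_qc()]: it
#' emulates the causal variant as actually called, i.e. one that survived
#' calling QC.  Each sample's table contains the variants for which that
#' sample has a non-reference call.
#'
#' @param cfg a [sim_config()].
#' @return list with `per_sample` (named list of variant tables for the
#'   affected samples), `control` (the control sample's table), `sets`
#'   (list of public [known_variant_set()]s), `truth` (the planted
#'   variant's key and coordinates) and `carrier_status` (named status
#'   vector over the F013-shaped pedigree for the planted variant, for
#'   [cosegregation_check()]).
#' @export
simulate_exomes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_background
  iv <- cfg$interval
  chrom <- sample(seq_along(chrom_lengths_mb), n, replace = TRUE,
                  prob = chrom_lengths_mb)
  pos <- floor(stats::runif(n, 1, chrom_lengths_mb[chrom] * 1e6))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  var_type <- sample(c("snv", "insertion", "deletion"), n, replace = TRUE,
                     prob = c(0.97, 0.015, 0.015))
  alt[var_type == "deletion"] <- "-"
  fclass <- sample(c("nonsynonymous", "splice_site", "synonymous", "other"),
                   n, replace = TRUE, prob = c(0.50, 0.04, 0.36, 0.10))
  known <- stats::runif(n) < cfg$p_known
  membership <- sapply(cfg$set_membership, function(p) known & stats::runif(n) < p)
  # a "known" variant absent from every set would be contradictory; anchor it
  orphan <- known & rowSums(membership) == 0L
  membership[orphan, 1] <- TRUE

  background <- data.frame(
    chromosome = paste0("Chr", chrom), position = pos, ref = ref, alt = alt,
    var_type = var_type, gene = paste0("GENE", seq_len(n)),
    functional_class = fclass,
    codon_change = NA_character_, stringsAsFactors = FALSE)

  # planted causal variant
  p_chrom <- norm_chrom(iv$chromosome)
  p_pos <- if (cfg$planted_inside_interval)
    floor(stats::runif(1, iv$start_bp, iv$end_bp + 1))
  else {
    repeat {
      cand <- floor(stats::runif(1, 1, 140e6))
      if (cand < iv$start_bp || cand > iv$end_bp) break
    }
    cand
  }
  p_ref <- sample(bases, 1)
  planted <- data.frame(
    chromosome = paste0("Chr", p_chrom), position = p_pos, ref = p_ref,
    alt = sample(setdiff(bases, p_ref), 1), var_type = "snv",
    gene = "CAUSAL", functional_class = "nonsynonymous",
    codon_change = random_codon_change(), stringsAsFactors = FALSE)
  truth_key <- variant_key(planted)

  sets <- lapply(names(cfg$set_membership), function(s)
    known_variant_set(s, background[membership[, s], , drop = FALSE]))
  names(sets) <- names(cfg$set_membership)

  carry_p <- ifelse(known, cfg$carry_known, cfg$carry_novel)
  sample_table <- function(is_control) {
    carried <- stats::runif(n) < carry_p
    tab <- background[carried, , drop = FALSE]
    tab <- cbind(tab, sample_qc_fields(nrow(tab)))
    tab$genotype <- ifelse(stats::runif(nrow(tab)) < 0.95, "het", "alt_hom")
    if (!is_control) {
      pl <- planted
      repeat {                      # causal variant as called: passed QC
        qcf <- sample_qc_fields(1)
        if (qc_passes(qcf)) break
      }
      pl <- cbind(pl, qcf)
      pl$genotype <- "het"
      tab <- rbind(tab, pl)
    }
    rownames(tab) <- NULL
    tab
  }
  per_sample <- setNames(
    lapply(cfg$affected_samples, function(s) sample_table(FALSE)),
    cfg$affected_samples)
  control <- sample_table(TRUE)

  ped <- f013_pedigree()
  mm <- ped$members
  status <- ifelse(mm$phenotype == "affected", "carrier_het",
            ifelse(mm$below_onset_age, "carrier_het", "noncarrier"))
  names(status) <- mm$id
  if (!cfg$planted_cosegregating) {
    aff <- mm$id[mm$phenotype == "affected"]
    status[aff[1]] <- "noncarrier"
  }

  list(per_sample = per_sample, control = control, sets = sets,
       truth = list(key = truth_key, chromosome = planted$chromosome,
                    position = planted$position, ref = planted$ref,
                    alt = planted$alt),
       carrier_status = status)
}

#' Write a simulated exome dataset to a directory
#'
#' Writes the per-sample and control variant tables, the public sets (as
#' 4-column TSVs) and the truth record (JSON) produced by
#' [simulate_exomes()].
#'
#' @param sim a [simulate_exomes()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulated_exomes <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$per_sample))
    write_variants_tsv(sim$per_sample[[s]],
                       file.path(dir, paste0(gsub(":", "_", s), ".tsv")))
  write_variants_tsv(sim$control, file.path(dir, "control.tsv"))
  for (s in names(sim$sets)) {
    keys <- do.call(rbind, strsplit(sim$sets[[s]]$keys, ":", fixed = TRUE))
    df <- data.frame(chromosome = keys[, 1], position = as.numeric(keys[, 2]),
                     ref = keys[, 3], alt = keys[, 4])
    utils::write.table(df, file.path(dir, paste0(s, ".tsv")), quote = FALSE,
                       row.names = FALSE, sep = "\t")
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
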