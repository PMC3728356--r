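sample_variant_df <- function(keys, genotype = "het", fclass = NULL,
                              var_type = NULL) {
  if (!length(keys))
    return(data.frame(chromosome = character(0), position = numeric(0),
                      ref = character(0), alt = character(0),
                      var_type = character(0),
                      functional_class = character(0),
                      genotype = character(0), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  n <- nrow(parts)
  data.frame(chromosome = parts[, 1], position = as.numeric(parts[, 2]),
             ref = parts[, 3], alt = parts[, 4],
             var_type = var_type %||% rep("snv", n),
             functional_class = fclass %||% rep("nonsynonymous", n),
             genotype = rep_len(genotype, n), stringsAsFactors = FALSE)
}

test_that("the functional filter keeps NS/SS/Indel classes only", {
  df <- data.frame(
    chromosome = "Chr1", position = 1:5, ref = "A", alt = c("T", "T", "T", "-", "T"),
    var_type = c("snv", "snv", "snv", "deletion", "snv"),
    functional_class = c("nonsynonymous", "synonymous", "splice_site",
                         "splice_site", "other"),
    stringsAsFactors = FALSE)
  kept <- functional_filter(df)
  expect_equal(kept$position, c(1, 3, 4))
  # a splice-site deletion is kept (the SYNE1-style case)
  expect_true(4 %in% kept$position)
  # missing annotation on an SNV is a record-level error
  df$functional_class[2] <- NA
  expect_error(functional_filter(df), class = "lx_missing_annotation")
  # census oracle on a random table
  set.seed(21)
  n <- 400
  rnd <- data.frame(chromosome = "Chr2", position = seq_len(n), ref = "G",
                    alt = "C",
                    var_type = sample(c("snv", "insertion", "deletion"), n,
                                      TRUE, prob = c(0.9, 0.05, 0.05)),
                    functional_class = sample(c("nonsynonymous", "splice_site",
                                                "synonymous", "other"),
                                              n, TRUE),
                    stringsAsFactors = FALSE)
  manual <- sum(rnd$var_type != "snv" |
                  rnd$functional_class %in% c("nonsynonymous", "splice_site"))
  expect_equal(nrow(functional_filter(rnd)), manual)
})

test_that("known-set subtraction is a set complement, order-independent", {
  keys <- paste0("1:", 1:100, ":A:T")
  recs <- sample_variant_df(keys)
  set.seed(31)
  in_a <- sample(c(TRUE, FALSE), 100, TRUE)
  in_b <- sample(c(TRUE, FALSE), 100, TRUE)
  set_a <- known_variant_set("a", recs[in_a, ])
  set_b <- known_variant_set("b", recs[in_b, ])
  out <- subtract_known(recs, list(set_a, set_b))
  expect_equal(variant_key(out), keys[!(in_a | in_b)])
  expect_equal(subtract_known(recs, list(set_b, set_a)), out)
  expect_equal(subtract_known(recs, list()), recs)     # empty set list: identity
  # commutes with the functional filter
  recs$var_type <- sample(c("snv", "deletion"), 100, TRUE)
  recs$alt[recs$var_type == "deletion"] <- "-"
  recs$functional_class <- sample(c("nonsynonymous", "synonymous"), 100, TRUE)
  sets <- list(known_variant_set("a", recs[in_a, ]))
  expect_equal(functional_filter(subtract_known(recs, sets)),
               subtract_known(functional_filter(recs), sets))
})

test_that("shared_by intersects non-reference calls across samples", {
  keys <- paste0("5:", 1:60, ":G:A")
  set.seed(41)
  tabs <- list(
    s1 = sample_variant_df(keys[1:40]),
    s2 = sample_variant_df(keys[20:55]),
    s3 = sample_variant_df(keys[30:60]))
  expect_equal(shared_by(tabs, "s1"), tabs$s1)         # single sample: identity
  triple <- shared_by(tabs, c("s1", "s2", "s3"))
  expect_equal(variant_key(triple), keys[30:40])       # oracle set intersection
  # a reference-homozygous call does not count as shared
  tabs$s2$genotype[tabs$s2$position == 35] <- "ref_hom"
  expect_false("5:35:G:A" %in%
                 variant_key(shared_by(tabs, c("s1", "s2", "s3"))))
  expect_error(shared_by(tabs, c("s1", "nope")), class = "lx_unknown_sample")
})

test_that("codon-change strings translate under the standard genetic code", {
  expect_equal(translate_codon_change("GTG-aTG", 1773), "V1773M")
  expect_equal(translate_codon_change("GAG-tAG", 217), "E217X")   # stop as X
  expect_equal(translate_codon_change("AAA-AAA", 5), "K5K")       # synonymous
  # every annotated fixture row is internally consistent
  cv <- candidate_variants()
  snvs <- cv[cv$codon_change != ".", ]
  for (i in seq_len(nrow(snvs))) {
    idx <- as.integer(gsub("[A-Z]", "", snvs$substitution[i]))
    expect_equal(translate_codon_change(snvs$codon_change[i], idx),
                 snvs$substitution[i])
  }
  expect_error(translate_codon_change("GT-aTG", 1), class = "lx_bad_codon")
  expect_error(translate_codon_change("GTG-acG", 1), class = "lx_bad_codon")
  expect_error(translate_codon_change("XTG-ATG", 1), class = "lx_bad_codon")
})

test_that("co-segregation follows the dominant-het rule with onset-age amnesty", {
  ped <- f013_pedigree()
  m <- ped$members
  status <- ifelse(m$phenotype == "affected", "carrier_het",
            ifelse(m$below_onset_age, "carrier_het", "noncarrier"))
  names(status) <- m$id
  # all 11 patients het, unaffecteds noncarrier, young carriers permitted
  expect_equal(cosegregation_check(ped, status)$verdict, "cosegregates")
  # one affected noncarrier breaks it, and is named
  bad <- status; bad[["IV:5"]] <- "noncarrier"
  res <- cosegregation_check(ped, bad)
  expect_equal(res$verdict, "fails")
  expect_equal(res$violations, "IV:5")
  # an affected homozygous carrier also breaks the het model
  bad2 <- status; bad2[["IV:17"]] <- "carrier_hom"
  expect_equal(cosegregation_check(ped, bad2)$verdict, "fails")
  # untyped members are ignored
  part <- status; part[1:20] <- "untyped"
  expect_equal(cosegregation_check(ped, part)$verdict, "cosegregates")
  # random assignments agree with a direct predicate evaluation
  set.seed(51)
  for (rep in 1:20) {
    st <- sample(c("carrier_het", "carrier_hom", "noncarrier", "untyped"),
                 nrow(m), TRUE, prob = c(0.4, 0.05, 0.45, 0.1))
    names(st) <- m$id
    manual_ok <- all(
      st[m$phenotype == "affected" & st[m$id] != "untyped"] == "carrier_het") &&
      all(st[m$phenotype == "unaffected" & !m$below_onset_age &
               st[m$id] != "untyped"] == "noncarrier")
    expect_equal(cosegregation_check(ped, st)$verdict == "cosegregates",
                 manual_ok)
  }
})

test_that("the cascade applies stages in order with a whole/locus ledger", {
  set.seed(61)
  sim <- simulate_exomes(sim_config(n_background = 1200, seed = 61))
  kept <- lapply(sim$per_sample, function(tab) apply_qc(tab)$kept)
  res <- run_cascade(kept, sim$sets,
                     known_variant_set("control", apply_qc(sim$control)$kept),
                     dfna56_interval())
  led <- as.data.frame(res$ledger)
  expect_equal(unique(led$stage),
               c("NS/SS/Indel", "Not in public sets",
                 "Not in public sets + control"))
  expect_true(all(led$locus <= led$whole))
  expect_true(all(led$whole >= 0))
  # counts never increase down stages for a fixed combination
  for (cmb in unique(led$combination)) {
    sub <- led[led$combination == cmb, ]
    expect_true(all(diff(sub$whole) <= 0))
    expect_true(all(diff(sub$locus) <= 0))
  }
  # ... nor across added intersected samples within a stage
  cum <- c("IV:5", "IV:5+IV:17", "IV:5+IV:17+IV:31")
  for (st in unique(led$stage)) {
    sub <- led[led$stage == st, ]
    expect_true(all(diff(sub$whole[match(cum, sub$combination)]) <= 0))
  }
  # every stage output is a key-subset of its input
  stage1 <- functional_filter(kept[[1]])
  stage2 <- subtract_known(stage1, sim$sets)
  expect_true(all(variant_key(stage2) %in% variant_key(stage1)))
  expect_true(all(variant_key(stage1) %in% variant_key(kept[[1]])))
  # the planted causal variant is the final candidate
  expect_true(sim$truth$key %in% variant_key(res$final))
})

test_that("the eight-candidate fixture yields exactly the in-locus TNC variant", {
  cv <- candidate_variants()
  expect_equal(nrow(cv), 8)
  final <- in_interval(cv, dfna56_interval())
  expect_equal(nrow(final), 1)
  expect_equal(final$gene, "TNC")
  expect_equal(final$position, 116843116)
  expect_equal(sub("^Chr", "", final$chromosome), "9")
})

test_that("empty input produces an all-zero ledger", {
  none <- sample_variant_df(character(0))
  res <- run_cascade(list(a = none, b = none),
                     sets = list(known_variant_set("s", none)),
                     control_set = known_variant_set("c", none),
                     interval = dfna56_interval())
  expect_true(all(res$ledger$whole == 0))
  expect_true(all(res$ledger$locus == 0))
  expect_equal(nrow(res$final), 0)
})
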