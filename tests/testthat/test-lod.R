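test_that("Z(0.5) is exactly zero and phase-known LOD matches m*log10(2)", {
  cs <- analytic_ped_case(10)
  expect_equal(lod(cs$ped, cs$gt, cs$model, 0.5), 0)
  expect_equal(lod(cs$ped, cs$gt, cs$model, 0), 10 * log10(2), tolerance = 1e-9)
  expect_equal(round(lod(cs$ped, cs$gt, cs$model, 0), 4), 3.0103)
  # interior theta follows the same closed form, Z = m*log10(2(1-theta))
  for (th in c(0.1, 0.25, 0.4))
    expect_equal(lod(cs$ped, cs$gt, cs$model, th), 10 * log10(2 * (1 - th)),
                 tolerance = 1e-9)
})

test_that("data impossible even at theta = 0.5 raise an impossible-data error", {
  dm <- disease_model()          # zero phenocopy: an affected dd is impossible
  mk <- marker_locus("M", "1", n_alleles = 2)
  ped <- quick_ped(c("fa", "mo", "k1"), c(NA, NA, "fa"), c(NA, NA, "mo"),
                   c("male", "female", "male"),
                   c("unaffected", "unaffected", "affected"))
  dm0 <- disease_model(0)        # and the disease allele has frequency 0
  expect_error(lod(ped, empty_gt(mk, ped), dm0, 0.1),
               class = "lx_impossible_data")
})

test_that("LOD curves report grid values, refined optimum and tie rules", {
  set.seed(55)
  dm <- disease_model()
  mk <- marker_locus("M", "9", n_alleles = 8)
  gd <- gene_drop(f013_pedigree(), dm, mk, 0.1, founder_carrier = "I:1")
  cv <- lod_curve(gd$ped, gd$genotypes, dm)
  expect_s3_class(cv, "lod_curve")
  expect_length(cv$lod_values, 6)
  expect_equal(cv$lod_values[6], 0)                   # Z(0.5) grid point
  expect_gte(cv$z_max, max(cv$lod_values) - 1e-9)     # refinement only improves
  expect_true(cv$theta_max >= 0 && cv$theta_max <= 0.5)
  expect_equal(unname(coef(cv)), c(cv$z_max, cv$theta_max))
  # grid-only mode reproduces the grid argmax exactly
  cvg <- lod_curve(gd$ped, gd$genotypes, dm, refine = FALSE)
  i <- which.max(cvg$lod_values)
  expect_equal(cvg$theta_max, cvg$theta_grid[i])
  expect_equal(cvg$z_max, cvg$lod_values[i])
})

test_that("published-style grid rows reproduce their tabulated argmax", {
  grid <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  d9s177 <- lod_curve_from_values("D9S177", grid,
                                  c(4.57, 3.82, 2.99, 2.05, 1.01, 0))
  expect_equal(coef(d9s177), c(z_max = 4.57, theta_max = 0))
  # a row with an interior optimum: the grid argmax is the best grid point;
  # recovering the true interior optimum would need the likelihood itself
  d9s1690 <- lod_curve_from_values("D9S1690", grid,
                                   c(-13.39, -1.03, -0.05, 0.27, 0.25, 0))
  expect_equal(coef(d9s1690), c(z_max = 0.27, theta_max = 0.3))
  # all-zero curve: ties break toward the smallest grid theta
  flat <- lod_curve_from_values("flat", grid, rep(0, 6))
  expect_equal(unname(coef(flat)), c(0, 0))
})

test_that("LOD scores add over independent families", {
  set.seed(66)
  dm <- disease_model()
  mk <- marker_locus("M", "1", n_alleles = 4)
  ped <- nuclear_ped(3, phens = c("affected", "unaffected", "affected",
                                  "affected", "unaffected"))
  gd <- gene_drop(ped, dm, mk, 0.05, founder_carrier = "fa")
  cv <- lod_curve(gd$ped, gd$genotypes, dm, refine = FALSE)
  # two copies of one family double every Z
  both <- combine_families(cv, cv)
  expect_equal(both$lod_values, 2 * cv$lod_values)
  # adding a family without genotypes changes nothing
  cv0 <- lod_curve(ped, empty_gt(mk, ped), dm, refine = FALSE)
  expect_equal(cv0$lod_values, rep(0, 6))              # no data: Z == 0
  expect_equal(combine_families(cv, cv0)$lod_values, cv$lod_values)
  # per-family sum equals the LOD of the concatenated two-family pedigree
  m2 <- gd$ped$members
  m2$id <- paste0("B", m2$id)
  m2$father_id <- ifelse(is.na(m2$father_id), NA, paste0("B", m2$father_id))
  m2$mother_id <- ifelse(is.na(m2$mother_id), NA, paste0("B", m2$mother_id))
  joint <- pedigree(rbind(gd$ped$members, m2), family_id = "joint")
  calls2 <- gd$genotypes$calls
  calls2$id <- paste0("B", calls2$id)
  gt_joint <- genotype_table(mk, rbind(gd$genotypes$calls, calls2), joint)
  cv_joint <- lod_curve(joint, gt_joint, dm, refine = FALSE)
  expect_equal(cv_joint$lod_values, both$lod_values, tolerance = 1e-9)
  # mismatched grids refuse to combine
  cv_bad <- lod_curve_from_values("x", c(0, 0.25, 0.5), c(1, 0.5, 0))
  expect_error(combine_families(cv, cv_bad), class = "lx_mismatched_grid")
})

test_that("the linked interval is defined by flanking markers symmetrically", {
  map <- dfna56_marker_map()
  iv <- define_interval(map, "D9S1677", "D9S1838")
  expect_equal(iv$start_bp, 110981204)
  expect_equal(iv$end_bp, 139519106)
  expect_equal(interval_span_bp(iv), 28537902)
  expect_equal(interval_span_mb(iv), 28.54)
  # reversed argument order gives the identical interval
  expect_equal(define_interval(map, "D9S1838", "D9S1677"), iv)
  # same marker twice: zero-length interval containing its position
  same <- define_interval(map, "D9S177", "D9S177")
  expect_equal(same$start_bp, same$end_bp)
  expect_equal(interval_span_bp(same), 0)
  # markers on different chromosomes refuse to pair
  map2 <- map
  map2$chrom[map2$name == "D9S1838"] <- "10"
  expect_error(define_interval(map2, "D9S1677", "D9S1838"),
               class = "lx_different_chromosomes")
})

test_that("interval membership is closed, 1-based and chr-prefix insensitive", {
  map <- dfna56_marker_map()
  iv <- define_interval(map, "D9S1677", "D9S1838")
  rec <- data.frame(chromosome = c("Chr9", "chr9", "9", "Chr10", "Chr9"),
                    position = c(iv$start_bp, iv$end_bp, iv$start_bp - 1,
                                 iv$start_bp + 5, iv$end_bp + 1))
  expect_equal(nrow(in_interval(rec, iv)), 2)   # both boundary rows kept
  # random records agree with a direct range scan
  set.seed(77)
  rnd <- data.frame(chromosome = sample(c("Chr9", "Chr8"), 500, TRUE),
                    position = floor(runif(500, 1e8, 1.5e8)))
  manual <- rnd[rnd$chromosome == "Chr9" & rnd$position >= iv$start_bp &
                  rnd$position <= iv$end_bp, ]
  expect_equal(in_interval(rnd, iv), manual)
})

test_that("interval writers emit BED (0-based half-open) and JSON", {
  iv <- dfna56_interval()
  bed <- withr::local_tempfile(fileext = ".bed")
  write_interval_bed(iv, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.numeric(fields[2]), iv$start_bp - 1)
  expect_equal(as.numeric(fields[3]), iv$end_bp)
  js <- withr::local_tempfile(fileext = ".json")
  write_interval_json(iv, js)
  expect_equal(jsonlite::read_json(js)$left_marker, "D9S1677")
})
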