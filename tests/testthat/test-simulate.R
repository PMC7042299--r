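test_that("the same seed reproduces the simulation exactly", {
  a <- simulate_cohort(tiny_sim_config(seed = 4))
  b <- simulate_cohort(tiny_sim_config(seed = 4))
  expect_equal(a$variants, b$variants)
  expect_equal(a$genotypes, b$genotypes)
  expect_equal(a$manifest, b$manifest)
  expect_equal(a$cohort$members, b$cohort$members)
  c_ <- simulate_cohort(tiny_sim_config(seed = 5))
  expect_false(identical(a$variants, c_$variants))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(consequence_mix = c(
    missense = 0.5, indel = 0.2, nonsense = 0.2, splice = 0.2)), "sum to 1")
  expect_error(sim_config(n_families = 2, causal_genes = tibble::tibble(
    gene = "G", n_families = 5L, class = "lof")), "more families")
  expect_error(sim_config(chip_vaf_range = c(0.6, 0.2)), "chip_vaf_range")
  expect_error(sim_config(pedigree_shapes = c(index_only = 0.5, duo = 0.2,
                                              trio = 0.2, extended = 0.2)),
               "sum to 1")
})

test_that("per-patient background counts match the configured distribution", {
  cfg <- sim_config()
  set.seed(101)
  counts <- famprio:::sample_background_counts(1000, cfg)
  expect_true(all(counts >= 161 & counts <= 781))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 311), 3 * se + 5)
})

test_that("germline VAFs are binomial around 0.5 and the consequence mix is honored", {
  sim <- simulate_cohort(sim_config(seed = 31, n_families = 20))
  bg <- sim$variants[sim$variants$origin == "background", ]
  expect_gte(median(bg$vaf[bg$depth >= 20]), 0.47)
  expect_lte(median(bg$vaf[bg$depth >= 20]), 0.53)
  mix <- table(dplyr::case_when(
    bg$consequence == "missense" ~ "missense",
    bg$consequence %in% c("frameshift_indel", "inframe_indel") ~ "indel",
    bg$consequence == "nonsense" ~ "nonsense",
    bg$consequence == "splice_proximal" ~ "splice")) / nrow(bg)
  expect_equal(unname(mix["missense"]), 0.863, tolerance = 0.02)
  expect_equal(unname(mix["splice"]), 0.051, tolerance = 0.02)
  # chi-squared sanity check of the generated class counts against the mix
  obs <- table(factor(dplyr::case_when(
    bg$consequence == "missense" ~ "missense",
    bg$consequence %in% c("frameshift_indel", "inframe_indel") ~ "indel",
    bg$consequence == "nonsense" ~ "nonsense",
    TRUE ~ "splice"), c("missense", "indel", "nonsense", "splice")))
  p <- suppressWarnings(chisq.test(
    obs, p = c(0.863, 0.062, 0.024, 0.051))$p.value)
  expect_gt(p, 0.001)
})

test_that("CHIP contaminants are private to one individual and VAF-bounded", {
  sim <- simulate_cohort(tiny_sim_config(seed = 9))
  chip <- sim$variants[sim$variants$origin == "chip", ]
  expect_equal(nrow(chip), 1)
  expect_true(chip$gene %in% c("TET2", "DNMT3A", "ASXL1"))
  expect_true(chip$vaf >= 0.08 & chip$vaf <= 0.52)  # binomial rounding slack
  g <- sim$genotypes[sim$genotypes$variant_id == chip$variant_id, ]
  expect_equal(sum(g$carrier == 1, na.rm = TRUE), 1)
  expect_equal(g$individual_id[g$carrier == 1], chip$carrier_id)
  # constructor-level checks
  row <- inject_chip_contaminant("F1_I1", "F1", "TET2", vaf = 0.46,
                                 depth = 100)
  expect_equal(row$alt_depth / row$depth, 0.46, tolerance = 0.01)
  expect_error(inject_chip_contaminant("F1_I1", "F1", "TET2", vaf = 1.2),
               "vaf")
})

test_that("injected causal variants are shared by affected relatives and satisfy the criteria", {
  sim <- simulate_cohort(tiny_sim_config(seed = 2))
  causal <- sim$variants[sim$variants$origin == "causal", ]
  expect_true(all(causal$vaf > 0.30))
  expect_true(all(is.na(causal$exac_af)))
  expect_true(all(causal$canonical))
  for (vid in causal$variant_id) {
    g <- sim$genotypes[sim$genotypes$variant_id == vid, ]
    mem <- sim$cohort$members[sim$cohort$members$family_id == g$family_id[1], ]
    aff <- mem$individual_id[mem$affection == "affected"]
    expect_true(all(g$carrier[g$individual_id %in% aff] == 1))
    expect_true(all(g$carrier[!g$individual_id %in% aff] == 0))
  }
  gl <- attr(sim$manifest, "gene_level")
  expect_true(gl$expected_recoverable[gl$gene == "CGENE1"])  # LoF x2
  expect_true(gl$expected_recoverable[gl$gene == "CGENE2"])  # missense x3
})

test_that("a spoiled injected variant is missed and counted correctly", {
  sim <- simulate_cohort(tiny_sim_config(seed = 6))
  v <- sim$variants
  spoil <- v$origin == "causal" & v$gene == "CGENE1"
  v$alt_depth[spoil] <- as.integer(round(0.2 * v$depth[spoil]))
  v$vaf[spoil] <- v$alt_depth[spoil] / v$depth[spoil]
  attr(v, "sim_id") <- attr(sim$variants, "sim_id")
  rep <- run_discovery_pipeline(sim$cohort, v, sim$genotypes)
  ev <- evaluate_recovery(rep, sim$manifest)
  expect_true("CGENE1" %in% ev$missed)
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$n_false_inclusions, 0)
})

test_that("recovery evaluation guards run identity and empty manifests", {
  sim1 <- simulate_cohort(tiny_sim_config(seed = 1))
  sim2 <- simulate_cohort(tiny_sim_config(seed = 2))
  rep1 <- run_discovery_pipeline(sim1$cohort, sim1$variants, sim1$genotypes)
  expect_error(evaluate_recovery(rep1, sim2$manifest), "different runs")
  none <- simulate_cohort(tiny_sim_config(
    seed = 3, causal_genes = tibble::tibble(
      gene = character(), n_families = integer(), class = character()),
    chip_n = 0))
  rep0 <- run_discovery_pipeline(none$cohort, none$variants, none$genotypes)
  ev0 <- evaluate_recovery(rep0, none$manifest)
  expect_true(is.na(ev0$sensitivity))
})

test_that("written simulations replay cleanly through the file readers", {
  sim <- simulate_cohort(tiny_sim_config(seed = 8, background_mean = 15,
                                         background_range = c(5, 60)))
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  co <- read_pedigree(paths["ped"], paths["pheno"])
  expect_equal(co$members, sim$cohort$members)
  v <- read_variants(paths["vcf"], paths["anno"], co)
  rep <- attr(v, "load_report")
  expect_equal(rep$records, length(unique(sim$variants$variant_id)))
  expect_equal(rep$unannotated, 0)
  # the original carrier rows reappear with identical depths and VAFs
  key <- function(d) paste(d$variant_id, d$carrier_id)
  m <- match(key(sim$variants), key(v))
  expect_false(anyNA(m))
  expect_equal(v$vaf[m], sim$variants$vaf)
  expect_equal(v$consequence[m], sim$variants$consequence)
  # genotype matrix round trip
  gw <- readr::read_tsv(paths["geno"], show_col_types = FALSE)
  expect_equal(nrow(gw), length(unique(sim$genotypes$variant_id)))
})
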