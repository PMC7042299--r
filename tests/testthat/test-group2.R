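test_that("per-variant criteria keep the germline-range rare damaging profile", {
  keep <- make_variant(vaf = 0.48)  # missense, 2 damaging, ExAC absent
  out <- apply_variant_criteria(keep)
  expect_equal(nrow(out), 1)
  expect_equal(out$segregation_status, "untestable")

  drop_cases <- dplyr::bind_rows(
    make_variant(vaf = 0.25, consequence = "nonsense"),          # criterion i
    make_variant(vaf = 0.30),                                    # boundary, strict
    make_variant(consequence = "splice_proximal", splice_offset = 5L), # ii
    make_variant(consequence = "synonymous"),                    # ii
    make_variant(canonical = FALSE),                             # ii
    make_variant(exac_af = 2e-4),                                # iv
    make_variant(polyphen2 = "tolerated", mutation_taster = "missing") # v
  )
  out2 <- apply_variant_criteria(drop_cases)
  expect_equal(nrow(out2), 0)
})

test_that("the per-criterion exclusion tally matches hand-computed fates", {
  # 20 variants with known per-criterion outcomes (rules applied by hand)
  v <- dplyr::bind_rows(
    lapply(1:6, function(i) make_variant(gene = paste0("K", i))),  # 6 keepers
    lapply(1:4, function(i) make_variant(gene = paste0("V", i), vaf = 0.2)),
    lapply(1:3, function(i) make_variant(gene = paste0("C", i),
                                         consequence = "other")),
    lapply(1:3, function(i) make_variant(gene = paste0("F", i),
                                         exac_af = 1e-3)),
    lapply(1:4, function(i) make_variant(gene = paste0("P", i),
                                         polyphen2 = "missing",
                                         mutation_taster = "missing",
                                         sift = "missing"))
  )
  expect_equal(nrow(v), 20)
  out <- apply_variant_criteria(v)
  expect_equal(nrow(out), 6)
  tally <- attr(out, "criteria_exclusions")
  expect_equal(tally$n_excluded[tally$criterion == "vaf"], 4)
  expect_equal(tally$n_excluded[tally$criterion == "consequence"], 3)
  expect_equal(tally$n_excluded[tally$criterion == "frequency"], 3)
  expect_equal(tally$n_excluded[tally$criterion == "predictors"], 4)
  expect_equal(tally$n_excluded[tally$criterion == "segregation"], 0)
})

test_that("segregation-refuted variants are excluded; missing entries are untestable", {
  v <- dplyr::bind_rows(
    make_variant(gene = "A", family_id = "F1", variant_id = "v1"),
    make_variant(gene = "B", family_id = "F1", variant_id = "v2"))
  seg <- tibble::tibble(variant_id = "v1", family_id = "F1",
                        status = "refuted")
  out <- apply_variant_criteria(v, seg)
  expect_equal(out$variant_id, "v2")
  expect_equal(out$segregation_status, "untestable")
  expect_equal(attr(out, "n_missing_segregation"), 1)
})

test_that("gene recurrence follows the LoF-2 / mixed-2 / missense-3 family rules", {
  v <- dplyr::bind_rows(
    # ADA-like: LoF in two families -> lof_recurrence
    make_variant(gene = "ADA", family_id = "FML056", consequence = "nonsense",
                 hgvs_p = "p.Gln3*"),
    make_variant(gene = "ADA", family_id = "FML071",
                 consequence = "frameshift_indel", hgvs_p = "p.Glu88Argfs*34"),
    # GP6-like: nonsense + missense in two families -> mixed_recurrence
    make_variant(gene = "GP6", family_id = "FML055", consequence = "nonsense"),
    make_variant(gene = "GP6", family_id = "FML063"),
    # missense in two families only -> excluded
    make_variant(gene = "MIS2", family_id = "F1"),
    make_variant(gene = "MIS2", family_id = "F2"),
    # missense in three families -> missense_recurrence
    make_variant(gene = "MIS3", family_id = "F1"),
    make_variant(gene = "MIS3", family_id = "F2"),
    make_variant(gene = "MIS3", family_id = "F3"),
    # two variants in ONE family count once -> excluded
    make_variant(gene = "ONE", family_id = "F1", consequence = "nonsense"),
    make_variant(gene = "ONE", family_id = "F1", consequence = "nonsense",
                 pos = 999)
  )
  agg <- aggregate_gene_recurrence(v)
  reason <- function(g) agg$inclusion_reason[agg$gene == g]
  expect_equal(reason("ADA"), "lof_recurrence")
  expect_equal(reason("GP6"), "mixed_recurrence")
  expect_equal(reason("MIS3"), "missense_recurrence")
  expect_false(agg$included[agg$gene == "MIS2"])
  expect_false(agg$included[agg$gene == "ONE"])
  expect_true(all(mapply(function(a, l, m) setequal(a, union(l, m)),
                         agg$families_any, agg$families_lof,
                         agg$families_missense)))
})

test_that("recurrence equals brute-force re-evaluation on random incidence", {
  # oracle: per-gene family counting done with base table() logic
  brute <- function(v, lof_min = 2, mixed_min = 2, mis_min = 3) {
    sapply(unique(v$gene), function(g) {
      rows <- v[v$gene == g, ]
      fl <- unique(rows$family_id[rows$consequence != "missense"])
      fm <- unique(rows$family_id[rows$consequence == "missense"])
      length(fl) >= lof_min ||
        (length(fl) >= 1 && length(unique(c(fl, fm))) >= mixed_min) ||
        length(fm) >= mis_min
    })
  }
  set.seed(99)
  for (r in 1:25) {
    n <- sample(5:40, 1)
    v <- dplyr::bind_rows(lapply(seq_len(n), function(i) make_variant(
      gene = paste0("G", sample.int(8, 1)),
      family_id = paste0("F", sample.int(6, 1)),
      consequence = sample(c("missense", "nonsense", "frameshift_indel"), 1),
      pos = i)))
    agg <- aggregate_gene_recurrence(v)
    want <- brute(v)
    expect_equal(setNames(agg$included, agg$gene), want[agg$gene])
    # order invariance
    shuffled <- aggregate_gene_recurrence(v[sample.int(nrow(v)), ])
    expect_equal(shuffled[order(shuffled$gene), c("gene", "included")],
                 agg[order(agg$gene), c("gene", "included")])
  }
})

test_that("cross-reference rescue needs a passing variant and a list hit", {
  v <- dplyr::bind_rows(
    make_variant(gene = "NAPRT1", family_id = "FML064",
                 consequence = "inframe_indel", hgvs_p = "p.Val216_Phe219dup"),
    make_variant(gene = "SH2B3", family_id = "F9", hgvs_p = "p.Ala49Thr"),
    make_variant(gene = "LONER", family_id = "F1"))
  passing <- apply_variant_criteria(v)
  agg <- aggregate_gene_recurrence(passing)
  expect_false(any(agg$included))
  lists <- external_candidate_lists()
  rescued <- rescue_by_cross_reference(agg, passing, lists)
  expect_true(rescued$included[rescued$gene == "NAPRT1"])
  expect_equal(rescued$inclusion_reason[rescued$gene == "NAPRT1"],
               "cross_reference_rescue")
  expect_equal(rescued$rescue_source[rescued$gene == "NAPRT1"], "patnaik")
  expect_true(rescued$included[rescued$gene == "SH2B3"])
  expect_false(rescued$included[rescued$gene == "LONER"])
  # DNAH9 is listed but has no passing variant here: never rescued
  expect_false("DNAH9" %in% rescued$gene)
  # previously included genes are unchanged
  v2 <- dplyr::bind_rows(v, make_variant(gene = "LONER", family_id = "F2",
                                         consequence = "nonsense"),
                         make_variant(gene = "LONER", family_id = "F3",
                                      consequence = "nonsense"))
  agg2 <- aggregate_gene_recurrence(apply_variant_criteria(v2))
  resc2 <- rescue_by_cross_reference(agg2, v2, lists)
  expect_equal(resc2$inclusion_reason[resc2$gene == "LONER"],
               "lof_recurrence")
})

test_that("the synonymous splice scan returns novel flagged synonymous variants only", {
  v <- dplyr::bind_rows(
    make_variant(gene = "S1", consequence = "synonymous"),
    make_variant(gene = "S2", consequence = "synonymous"),
    make_variant(gene = "S3", consequence = "synonymous", exac_af = 1e-5),
    make_variant(gene = "M1"))
  v$splice_impact <- c(0.9, 0.1, 0.9, 0.9)
  out <- scan_synonymous_splicing(v)
  expect_equal(out$gene, "S1")  # S2 unflagged, S3 not novel, M1 not synonymous
  expect_error(scan_synonymous_splicing(v[setdiff(names(v), "splice_impact")]),
               "splice_impact")
})

test_that("sporadic-AML overlap is flagged per gene with an integer percentage", {
  agg <- tibble::tibble(
    gene = c(paste0("G", 1:39), sporadic_aml_genes()[1:26]),
    included = TRUE, n_any = 1L,
    inclusion_reason = "lof_recurrence")
  out <- annotate_sporadic_overlap(agg, sporadic_aml_genes())
  expect_true(out$sporadic_aml[out$gene == "TET2"])
  expect_equal(attr(out, "sporadic_overlap_pct"), 40)  # 26 of 65
  empty <- annotate_sporadic_overlap(agg[agg$gene == "NONE", ],
                                     sporadic_aml_genes())
  expect_true(is.na(attr(empty, "sporadic_overlap_pct")))
})

test_that("the pipeline recovers injected genes and honors the containment chain", {
  sim <- simulate_cohort(tiny_sim_config(seed = 21))
  rep <- run_discovery_pipeline(sim$cohort, sim$variants, sim$genotypes,
                                external_lists = external_candidate_lists(),
                                sporadic_genes = sporadic_aml_genes())
  gl <- attr(sim$manifest, "gene_level")
  expected <- gl$gene[gl$expected_recoverable]
  included <- rep$gene_aggregates$gene[rep$gene_aggregates$included]
  expect_true(all(expected %in% included))
  # containment chain: final subset of passing subset of pre-filtered
  pre <- prefilter_variants(sim$variants)
  expect_true(all(rep$variants_final$variant_id %in%
                    rep$variants_passing$variant_id))
  expect_true(all(rep$variants_passing$variant_id %in% pre$variant_id))
  # every included gene has at least one passing variant
  expect_true(all(included %in% rep$variants_passing$gene |
                    included %in% rep$gene_aggregates$gene[
                      rep$gene_aggregates$n_any >= 1]))
  # row-order invariance of the gene set
  shuf <- sim$variants[sample.int(nrow(sim$variants)), ]
  attr(shuf, "sim_id") <- attr(sim$variants, "sim_id")
  rep2 <- run_discovery_pipeline(sim$cohort, shuf, sim$genotypes)
  expect_setequal(rep2$gene_aggregates$gene[rep2$gene_aggregates$included],
                  rep$gene_aggregates$gene[rep$gene_aggregates$included])
})

test_that("a cohort with no recurrence and no rescue yields an empty gene list", {
  v <- dplyr::bind_rows(lapply(1:5, function(i) make_variant(
    gene = paste0("U", i), family_id = paste0("F", i),
    carrier_id = paste0("F", i, "_I1"), pos = i)))
  members <- dplyr::bind_rows(lapply(1:5, function(i)
    make_members(1, family_id = paste0("F", i))))
  co <- new_cohort(members)
  rep <- run_discovery_pipeline(co, v)
  expect_equal(nrow(rep$variants_final), 0)
  expect_equal(sum(rep$gene_aggregates$included), 0)
  expect_setequal(rep$zero_variant_families, paste0("F", 1:5))
})
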