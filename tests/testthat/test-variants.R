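test_that("VAF is alt/depth with depth-0 guarded", {
  expect_equal(compute_vaf(30, 62), 30 / 62, tolerance = 1e-12)
  expect_equal(compute_vaf(0, 50), 0)
  expect_true(is.na(compute_vaf(0, 0)))
  expect_error(compute_vaf(10, 5), "exceeds")
  expect_error(compute_vaf(-1, 5), "non-negative")
  # a germline-range call at the published threshold is strict
  expect_true(0.454 > 0.30)
  expect_false(0.30 > 0.30)
})

test_that("HGVS consequence classification handles the canonical cases", {
  cases <- tibble::tribble(
    ~hgvs_c,            ~hgvs_p,              ~expect,            ~offset,
    "c.370C>T",         "p.Arg124X",          "nonsense",          NA,
    "c.183_184delinsCT", "p.Lys62X",          "nonsense",          NA,
    "c.258+2T>C",       NA,                   "splice_proximal",   2,
    "c.2505-1G>T",      NA,                   "splice_proximal",  -1,
    "c.3626+5G>C",      NA,                   "splice_proximal",   5,
    "c.1336delA",       "p.Lys446fs",         "frameshift_indel",  NA,
    "c.1445delA",       "p.His482Profs*27",   "frameshift_indel",  NA,
    "c.3G>A",           "p.Met1?",            "start_lost",        NA,
    "c.1061C>T",        "p.Thr354Met",        "missense",          NA,
    "c.646_657dup",     "p.Val216_Phe219dup", "inframe_indel",     NA,
    "c.330G>A",         "p.Thr110Thr",        "synonymous",        NA
  )
  got <- classify_consequence(cases$hgvs_c, cases$hgvs_p)
  expect_equal(got$consequence, cases$expect)
  expect_equal(got$splice_offset, as.integer(cases$offset))
  # offset is parsed iff splice_proximal
  expect_true(all(is.na(got$splice_offset) !=
                    (got$consequence == "splice_proximal")))
})

test_that("splice offsets match an independent regex reference on fuzzed input", {
  set.seed(42)
  n <- 200
  base <- sample.int(5000, n)
  off <- sample(c(-8:-1, 1:8), n, replace = TRUE)
  hg <- sprintf("c.%d%+dG>A", base, off)
  got <- classify_consequence(hg)
  # reference parser: independent regex pulling the signed offset
  ref <- as.integer(sub("^c\\.[0-9]+([+-][0-9]+).*$", "\\1", hg))
  expect_equal(got$splice_offset, ref)
  expect_true(all(got$consequence == "splice_proximal"))
})

test_that("raw-consequence fallback and unparseable input", {
  got <- classify_consequence(NA, NA, "missense_variant")
  expect_equal(got$consequence, "missense")
  expect_message(
    got2 <- classify_consequence("oddball", NA, NA),
    "could not be classified")
  expect_equal(got2$consequence, "other")
})

test_that("the pre-filter drops common, shallow, and segdup variants", {
  v <- dplyr::bind_rows(
    make_variant(gene = "A", exac_af = 0.01),
    make_variant(gene = "B", depth = 19),
    make_variant(gene = "C", segdup = TRUE),
    make_variant(gene = "D", gnomad_af = 0.006),
    make_variant(gene = "E", exac_af = 0.0005),
    make_variant(gene = "F")  # absent from both databases: passes
  )
  out <- prefilter_variants(v)
  expect_setequal(out$gene, c("E", "F"))
  excl <- attr(out, "exclusions")
  expect_equal(excl$n_excluded[excl$rule == "frequency"], 2)
  expect_equal(excl$n_excluded[excl$rule == "depth"], 1)
  expect_equal(excl$n_excluded[excl$rule == "segdup"], 1)
  # boundary: depth exactly 20 passes, af exactly 0.005 fails
  expect_equal(nrow(prefilter_variants(make_variant(depth = 20))), 1)
  expect_equal(nrow(prefilter_variants(make_variant(exac_af = 0.005))), 0)
})

test_that("the pre-filter is idempotent and empty-safe", {
  empty <- prefilter_variants(make_variant()[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(attr(empty, "exclusions")$n_excluded == 0))
  sim <- simulate_cohort(tiny_sim_config(seed = 3))
  once <- prefilter_variants(sim$variants)
  twice <- prefilter_variants(once)
  expect_equal(twice$variant_id, once$variant_id)
  expect_true(all(attr(twice, "exclusions")$n_excluded == 0))
})

test_that("predictor consensus needs 2 of 4 damaging; LoF is exempt", {
  prof <- function(...) tibble::tibble(
    polyphen2 = ..1, mutation_taster = ..2, sift = ..3, provean = ..4)
  expect_true(predictor_consensus(
    prof("damaging", "damaging", "tolerated", "missing"), "missense"))
  expect_false(predictor_consensus(
    prof("damaging", "missing", "missing", "missing"), "missense"))
  expect_true(predictor_consensus(
    prof("missing", "missing", "missing", "missing"), "nonsense"))
  expect_true(predictor_consensus(
    prof("missing", "missing", "missing", "missing"),
    "splice_proximal", splice_offset = -2))
  # a splice hit outside the canonical region is not exempt
  expect_false(predictor_consensus(
    prof("missing", "missing", "missing", "missing"),
    "splice_proximal", splice_offset = 5))
  # strict mode withdraws the exemption
  expect_false(predictor_consensus(
    prof("missing", "missing", "missing", "missing"), "nonsense",
    strict = TRUE))
})

write_test_vcf <- function(records, samples = "S1") {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

anno_row <- function(chrom, pos, ref, alt, gene = "G1") {
  tibble::tibble(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
                 gene = gene, transcript = "TX", canonical = TRUE,
                 hgvs_c = "c.100A>G", hgvs_p = "p.Ala34Arg",
                 consequence = "missense_variant",
                 exac_af = NA_real_, gnomad_af = NA_real_, segdup = FALSE,
                 polyphen2 = "damaging", mutation_taster = "tolerated",
                 sift = "damaging", provean = "missing")
}

test_that("VCF + annotation loading computes VAF from AD and reports tallies", {
  vcf <- write_test_vcf(c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:32,30:62",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:25,25:50"))
  anno <- tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::bind_rows(
    anno_row("1", 100, "A", "G"), anno_row("1", 200, "C", "T")), anno)
  v <- read_variants(vcf, anno)
  expect_equal(nrow(v), 2)
  expect_equal(v$vaf, c(30 / 62, 0.5), tolerance = 1e-12)
  expect_equal(v$consequence, c("missense", "missense"))
  rep <- attr(v, "load_report")
  expect_equal(rep$records, 2)
  expect_equal(rep$unannotated, 0)
})

test_that("zero-depth records are retained with a flag; unannotated dropped with warning", {
  vcf <- write_test_vcf("1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:0,0:0")
  anno <- tempfile(fileext = ".tsv")
  readr::write_tsv(anno_row("1", 100, "A", "G"), anno)
  v <- read_variants(vcf, anno)
  expect_equal(nrow(v), 1)
  expect_true(is.na(v$vaf))
  expect_equal(v$note, "no_depth")

  vcf2 <- write_test_vcf(c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:30,30:60",
    "1\t300\t.\tG\tC\t.\tPASS\t.\tGT:AD:DP\t0/1:30,30:60"))
  expect_warning(v2 <- read_variants(vcf2, anno), "no annotation")
  expect_equal(nrow(v2), 1)
  expect_equal(attr(v2, "load_report")$unannotated, 1)
})

test_that("multi-allelic records are decomposed to biallelic rows", {
  vcf <- write_test_vcf(
    "1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:AD:DP\t1/2:10,20,30:60")
  anno <- tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::bind_rows(
    anno_row("1", 100, "A", "G"), anno_row("1", 100, "A", "T")), anno)
  v <- read_variants(vcf, anno)
  expect_equal(nrow(v), 2)
  expect_setequal(v$alt, c("G", "T"))
  expect_equal(sort(v$alt_depth), c(20, 30))
  expect_equal(attr(v, "load_report")$biallelic_rows, 2)
})

test_that("load report totals equal the file record count on a generated fixture", {
  n <- 100
  recs <- sprintf("1\t%d\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
                  seq_len(n) * 10, 30, 30, 60)
  vcf <- write_test_vcf(recs)
  anno <- tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::bind_rows(lapply(seq_len(n) * 10, function(p)
    anno_row("1", p, "A", "G"))), anno)
  v <- read_variants(vcf, anno)
  rep <- attr(v, "load_report")
  expect_equal(rep$records, n)
  expect_equal(rep$carrier_rows, n)
  expect_equal(nrow(v), n)
  expect_true(all(v$vaf >= 0 & v$vaf <= 1, na.rm = TRUE))
})
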