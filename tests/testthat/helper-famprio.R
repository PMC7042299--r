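# Shared test helpers: small builders for variants, pedigrees and
# simulation configs sized for fast test runs.

make_variant <- function(gene = "GENE1", family_id = "F1", carrier_id = "F1_I1",
                         vaf = 0.48, depth = 80,
                         consequence = "missense", splice_offset = NA_integer_,
                         exac_af = NA_real_, gnomad_af = NA_real_,
                         segdup = FALSE, canonical = TRUE,
                         polyphen2 = "damaging", mutation_taster = "damaging",
                         sift = "tolerated", provean = "missing",
                         hgvs_c = NA_character_, hgvs_p = NA_character_,
                         variant_id = NULL, pos = NULL) {
  pos <- pos %||% sample.int(1e6, 1)
  tibble::tibble(
    variant_id = variant_id %||% paste("1", pos, "A", "G", sep = ":"),
    chrom = "1", pos = pos, ref = "A", alt = "G",
    gene = gene, transcript = paste0("TX_", gene), canonical = canonical,
    hgvs_c = hgvs_c, hgvs_p = hgvs_p, consequence_raw = NA_character_,
    depth = as.integer(depth),
    alt_depth = as.integer(round(vaf * depth)),
    vaf = vaf, exac_af = exac_af, gnomad_af = gnomad_af, segdup = segdup,
    polyphen2 = polyphen2, mutation_taster = mutation_taster,
    sift = sift, provean = provean,
    family_id = family_id, carrier_id = carrier_id,
    consequence = consequence, splice_offset = splice_offset
  )
}

make_members <- function(n_affected = 2, n_unaffected = 0, family_id = "F1") {
  n <- n_affected + n_unaffected
  tibble::tibble(
    family_id = family_id,
    individual_id = paste0(family_id, "_I", seq_len(n)),
    father_id = NA_character_, mother_id = NA_character_,
    sex = rep(c("female", "male"), length.out = n),
    affection = c(rep("affected", n_affected), rep("unaffected", n_unaffected)),
    diagnosis = c(rep("MDS", n_affected), rep("none", n_unaffected)),
    age_at_onset = NA_real_,
    index_case = seq_len(n) == 1,
    sampled = TRUE
  )
}

tiny_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    n_families = 6,
    background_mean = 40, background_range = c(10, 150),
    n_background_genes = 3000,
    causal_genes = tibble::tibble(
      gene = c("CGENE1", "CGENE2"), n_families = c(2L, 3L),
      class = c("lof", "missense")),
    chip_n = 1,
    seed = seed)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
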