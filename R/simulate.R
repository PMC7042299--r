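# Synthetic familial cohort simulator.
#
# Generates cohorts with the statistical structure the discovery cascade
# assumes — per-patient rare-variant burdens, binomial germline VAFs
# centred on 0.5, the observed consequence mix, clonal-hematopoiesis (CHIP)
# contaminants confined to single individuals, and causal genes injected
# into a configurable number of families — so that every pipeline stage is
# testable without external data and recovery of injected signal can be
# measured against a manifest.

AA_REF <- c("Ala", "Gly", "Ser", "Thr", "Val", "Ile", "Pro")
AA_ALT <- c("Arg", "Trp", "Cys", "His", "Leu", "Gln", "Tyr")

#' Simulation configuration
#'
#' Defaults reproduce the structure of a 37-family exome discovery cohort:
#' a negative-binomial rare-variant burden with mean 311 per patient
#' truncated to the observed range 161-781, consequence mix 86.3% missense
#' / 6.2% indel / 2.4% nonsense / 5.1% splice-region, mean read depth 80
#' with a small deliberate low-depth fraction to exercise the pre-filter,
#' heterozygous germline VAFs as Binomial(depth, 0.5) draws, CHIP
#' contaminants with VAF in 0.10-0.50 confined to one individual, and
#' three injected causal genes (loss-of-function in 2 families, missense
#' in 3, mixed in 2) whose variants satisfy the discovery criteria by
#' construction.
#'
#' @param n_families number of families (default 37).
#' @param pedigree_shapes sampling distribution over family shapes
#'   `index_only` (one sampled affected), `duo` (two affected), `trio`
#'   (two affected + unaffected parent), `extended` (three affected + two
#'   unaffected).
#' @param background_mean,background_range,background_size negative-binomial
#'   mean, truncation range and size (dispersion) of the per-patient
#'   rare-variant count.
#' @param consequence_mix named fractions over
#'   `missense`/`indel`/`nonsense`/`splice`; must sum to 1.
#' @param depth_mean mean per-site read depth; `low_depth_rate` of sites
#'   instead draw around `low_depth_mean` (exercising the depth filter).
#' @param vaf_p binomial success probability for germline alt reads
#'   (default 0.5).
#' @param chip_n number of CHIP contaminants per cohort;
#'   `chip_vaf_range`/`chip_genes` control their VAF and gene.
#' @param causal_genes data frame `gene`, `n_families`, `class`
#'   (`lof`/`missense`/`mixed`) of injected recurrent causal genes.
#' @param exac_absent_frac,exac_range ExAC model: fraction of variants
#'   absent from the reference databases, and the log-uniform range of
#'   frequencies for those present.
#' @param predictor_damaging_prob per-tool damaging probability, named
#'   `causal` and `background`.
#' @param n_background_genes size of the neutral background gene-symbol
#'   pool.
#' @param seed integer seed; the simulation is fully reproducible given the
#'   configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 37,
                       pedigree_shapes = c(index_only = 0.38, duo = 0.20,
                                           trio = 0.22, extended = 0.20),
                       background_mean = 311,
                       background_range = c(161, 781),
                       background_size = 8,
                       consequence_mix = c(missense = 0.863, indel = 0.062,
                                           nonsense = 0.024, splice = 0.051),
                       depth_mean = 80, low_depth_rate = 0.03,
                       low_depth_mean = 12, segdup_rate = 0.02,
                       vaf_p = 0.5,
                       chip_n = 2, chip_vaf_range = c(0.10, 0.50),
                       chip_genes = c("TET2", "DNMT3A", "ASXL1"),
                       causal_genes = tibble(
                         gene = c("CGENE1", "CGENE2", "CGENE3"),
                         n_families = c(2L, 3L, 2L),
                         class = c("lof", "missense", "mixed")),
                       exac_absent_frac = 0.05,
                       exac_range = c(1e-5, 5e-3),
                       predictor_damaging_prob = c(causal = 0.9,
                                                   background = 0.15),
                       n_background_genes = 15000,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$causal_genes <- as_tibble(causal_genes)
  if (abs(sum(consequence_mix) - 1) > 1e-9) {
    stop("consequence_mix must sum to 1", call. = FALSE)
  }
  if (!setequal(names(consequence_mix),
                c("missense", "indel", "nonsense", "splice"))) {
    stop("consequence_mix must name missense, indel, nonsense, splice",
         call. = FALSE)
  }
  if (abs(sum(pedigree_shapes) - 1) > 1e-9) {
    stop("pedigree_shapes must sum to 1", call. = FALSE)
  }
  probs <- c(pedigree_shapes, exac_absent_frac, vaf_p,
             low_depth_rate, segdup_rate, predictor_damaging_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(cfg$causal_genes) &&
      any(cfg$causal_genes$n_families > n_families)) {
    stop("causal gene injected into more families than exist", call. = FALSE)
  }
  if (chip_vaf_range[1] < 0 || chip_vaf_range[2] > 1 ||
      chip_vaf_range[1] > chip_vaf_range[2]) {
    stop("invalid chip_vaf_range", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# truncated negative-binomial per-patient rare-variant counts
sample_background_counts <- function(n, cfg) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- rnbinom(2 * (n - length(out)) + 10, mu = cfg$background_mean,
                    size = cfg$background_size)
    draw <- draw[draw >= cfg$background_range[1] &
                   draw <= cfg$background_range[2]]
    out <- c(out, draw)
  }
  out[seq_len(n)]
}

make_sim_family <- function(fid, shape) {
  base <- function(id, father, mother, sex, aff) {
    tibble(family_id = fid, individual_id = id, father_id = father,
           mother_id = mother, sex = sex, affection = aff)
  }
  m <- switch(shape,
    index_only = base("I1", NA, NA, "female", "affected"),
    duo = bind_rows(
      base("I2", NA, NA, "male", "affected"),
      base("I1", "I2", NA, "female", "affected")),
    trio = bind_rows(
      base("I2", NA, NA, "female", "affected"),
      base("I3", NA, NA, "male", "unaffected"),
      base("I1", "I3", "I2", "female", "affected")),
    extended = bind_rows(
      base("I2", NA, NA, "female", "affected"),
      base("I3", NA, NA, "male", "unaffected"),
      base("I1", "I3", "I2", "female", "affected"),
      base("I4", "I3", "I2", "male", "affected"),
      base("I5", "I3", "I2", "female", "unaffected")),
    stop("unknown pedigree shape: ", shape, call. = FALSE)
  )
  m$individual_id <- paste(fid, m$individual_id, sep = "_")
  m$father_id <- ifelse(is.na(m$father_id), NA,
                        paste(fid, m$father_id, sep = "_"))
  m$mother_id <- ifelse(is.na(m$mother_id), NA,
                        paste(fid, m$mother_id, sep = "_"))
  m
}

variant_hgvs <- function(class, idx) {
  aap <- 100 + (idx %% 400)
  ref3 <- AA_REF[1 + (idx %% length(AA_REF))]
  alt3 <- AA_ALT[1 + (idx %% length(AA_ALT))]
  cpos <- 3 * aap - 1
  switch(class,
    missense = list(hgvs_c = sprintf("c.%dC>T", cpos),
                    hgvs_p = sprintf("p.%s%d%s", ref3, aap, alt3),
                    raw = "missense_variant"),
    nonsense = list(hgvs_c = sprintf("c.%dC>T", cpos),
                    hgvs_p = sprintf("p.%s%dTer", ref3, aap),
                    raw = "stop_gained"),
    frameshift = list(hgvs_c = sprintf("c.%ddelA", cpos),
                      hgvs_p = sprintf("p.%s%dfs", ref3, aap),
                      raw = "frameshift_variant"),
    inframe = list(hgvs_c = sprintf("c.%d_%ddel", cpos, cpos + 2),
                   hgvs_p = sprintf("p.%s%ddel", ref3, aap),
                   raw = "inframe_deletion"),
    splice = {
      off <- sample(c(-3:-1, 1:3), 1)
      list(hgvs_c = sprintf("c.%d%+dG>A", cpos, off), hgvs_p = NA_character_,
           raw = if (off > 0) "splice_donor_variant" else
             "splice_acceptor_variant")
    },
    stop("unknown variant class", call. = FALSE)
  )
}

#' Simulate a familial MDS/AML discovery cohort
#'
#' Fully reproducible given `cfg$seed`. Background variants are private to
#' one patient; injected causal variants are shared identically by all
#' affected (sampled) members of each chosen family and absent from
#' unaffected members; CHIP contaminants are present in exactly one
#' individual, never in relatives.
#'
#' @param cfg a [sim_config()].
#' @return a `fam_simulation`: list with `cohort` (a `fam_cohort`),
#'   `variants` (annotated variant x carrier tibble in the
#'   [read_variants()] schema plus an `origin` column), `genotypes` (long
#'   table for [segregation_table()]), `manifest` (injection manifest; the
#'   gene-level summary with `expected_recoverable` flags is attached as
#'   attribute `"gene_level"`), and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_cohort(cfg))
}

.simulate_cohort <- function(cfg) {
  fids <- sprintf("FAM%03d", seq_len(cfg$n_families))
  shapes <- sample(names(cfg$pedigree_shapes), cfg$n_families, replace = TRUE,
                   prob = cfg$pedigree_shapes)
  members <- bind_rows(mapply(make_sim_family, fids, shapes,
                              SIMPLIFY = FALSE))
  members$diagnosis <- NA_character_
  aff <- members$affection == "affected"
  members$diagnosis[aff] <- sample(
    c("MDS", "AML", "thrombocytopenia", "BMF/aplastic_anemia"),
    sum(aff), replace = TRUE, prob = c(0.35, 0.35, 0.15, 0.15))
  members$diagnosis[!aff] <- "none"
  members$age_at_onset <- ifelse(aff, pmin(pmax(round(rnorm(
    nrow(members), 40, 18)), 1), 88), NA_real_)
  members$index_case <- !duplicated(paste(members$family_id, aff)) & aff
  # guarantee the inclusion rule: the index case is always MDS or AML
  members$diagnosis[members$index_case] <- sample(
    c("MDS", "AML"), sum(members$index_case), replace = TRUE)
  members$sampled <- TRUE
  cohort <- new_cohort(members)

  patients <- members[aff, c("family_id", "individual_id")]
  n_pat <- nrow(patients)
  counts <- sample_background_counts(n_pat, cfg)
  n_bg <- sum(counts)

  bg <- tibble(
    family_id = rep(patients$family_id, counts),
    carrier_id = rep(patients$individual_id, counts)
  )
  mix <- cfg$consequence_mix
  cls4 <- sample(names(mix), n_bg, replace = TRUE, prob = mix)
  frame <- runif(n_bg) < 0.6
  cls <- ifelse(cls4 == "indel", ifelse(frame, "frameshift", "inframe"), cls4)
  low <- runif(n_bg) < cfg$low_depth_rate
  depth <- pmax(rpois(n_bg, ifelse(low, cfg$low_depth_mean, cfg$depth_mean)),
                1L)
  alt <- rbinom(n_bg, depth, cfg$vaf_p)
  alt <- pmin(pmax(alt, 1L), depth)
  absent <- runif(n_bg) < cfg$exac_absent_frac
  af <- 10^runif(n_bg, log10(cfg$exac_range[1]), log10(cfg$exac_range[2]))
  p_bg <- cfg$predictor_damaging_prob[["background"]]
  pred <- function(n, p) sample(c("damaging", "tolerated", "missing"), n,
                                replace = TRUE, prob = c(p, 1 - p - 0.05, 0.05))
  idx_v <- seq_len(n_bg)
  hg <- lapply(seq_len(n_bg), function(i) variant_hgvs(cls[i], i))
  bg <- bg |> mutate(
    gene = sprintf("BG%05d", sample.int(cfg$n_background_genes, n_bg,
                                        replace = TRUE)),
    class = cls,
    depth = depth, alt_depth = alt,
    exac_af = ifelse(absent, NA_real_, af),
    gnomad_af = ifelse(absent, NA_real_, pmin(af * runif(n_bg, 0.5, 2), 0.99)),
    segdup = runif(n_bg) < cfg$segdup_rate,
    canonical = runif(n_bg) > 0.03,
    polyphen2 = pred(n_bg, p_bg), mutation_taster = pred(n_bg, p_bg),
    sift = pred(n_bg, p_bg), provean = pred(n_bg, p_bg),
    hgvs_c = vapply(hg, `[[`, character(1), "hgvs_c"),
    hgvs_p = vapply(hg, function(x) x$hgvs_p %||% NA_character_,
                    character(1)),
    consequence_raw = vapply(hg, `[[`, character(1), "raw"),
    origin = "background"
  )

  # injected recurrent causal genes
  inj <- list()
  manifest <- list()
  if (nrow(cfg$causal_genes)) {
    for (i in seq_len(nrow(cfg$causal_genes))) {
      g <- cfg$causal_genes[i, ]
      fams <- sample(fids, g$n_families)
      classes <- switch(g$class,
        lof = rep("lof", g$n_families),
        missense = rep("missense", g$n_families),
        mixed = c("lof", rep("missense", g$n_families - 1)),
        stop("causal class must be lof, missense or mixed", call. = FALSE))
      for (k in seq_along(fams)) {
        fam <- fams[k]
        index_id <- cohort$families$index_case_id[
          cohort$families$family_id == fam]
        cls_k <- if (classes[k] == "lof") {
          sample(c("nonsense", "frameshift", "splice"), 1)
        } else "missense"
        d <- max(rpois(1, cfg$depth_mean), 25L)
        a <- rbinom(1, d, cfg$vaf_p)
        tries <- 0
        while (a / d <= 0.30 && tries < 50) {
          a <- rbinom(1, d, cfg$vaf_p); tries <- tries + 1
        }
        if (a / d <= 0.30) a <- ceiling(0.45 * d)
        h <- variant_hgvs(cls_k, 1000 * i + k)
        p_c <- cfg$predictor_damaging_prob[["causal"]]
        row <- tibble(
          family_id = fam, carrier_id = index_id, gene = g$gene,
          class = cls_k, depth = d, alt_depth = a,
          exac_af = NA_real_, gnomad_af = NA_real_,
          segdup = FALSE, canonical = TRUE,
          polyphen2 = if (cls_k == "missense") "damaging" else "missing",
          mutation_taster = if (cls_k == "missense") "damaging" else "missing",
          sift = pred(1, p_c), provean = pred(1, p_c),
          hgvs_c = h$hgvs_c, hgvs_p = h$hgvs_p %||% NA_character_,
          consequence_raw = h$raw,
          origin = "causal"
        )
        inj[[length(inj) + 1]] <- row
        manifest[[length(manifest) + 1]] <- tibble(
          gene = g$gene, family_id = fam, class = cls_k, chip = FALSE)
      }
    }
  }

  # CHIP contaminants: somatic clones confined to a single individual
  if (cfg$chip_n > 0) {
    chip_patients <- patients[sample.int(n_pat, min(cfg$chip_n, n_pat)), ]
    for (k in seq_len(nrow(chip_patients))) {
      gene <- sample(cfg$chip_genes, 1)
      vaf <- runif(1, cfg$chip_vaf_range[1], cfg$chip_vaf_range[2])
      row <- inject_chip_contaminant(
        chip_patients$individual_id[k], chip_patients$family_id[k],
        gene = gene, vaf = vaf, depth = max(rpois(1, cfg$depth_mean), 30L),
        .idx = 9000 + k)
      inj[[length(inj) + 1]] <- row
      manifest[[length(manifest) + 1]] <- tibble(
        gene = gene, family_id = chip_patients$family_id[k],
        class = row$class, chip = TRUE)
    }
  }

  variants <- bind_rows(bg, bind_rows(inj))
  n_v <- nrow(variants)
  variants$chrom <- as.character(sample(1:22, n_v, replace = TRUE))
  variants$pos <- 100000L + seq_len(n_v) * 37L
  is_indel <- variants$class %in% c("frameshift", "inframe")
  variants$ref <- ifelse(is_indel, "AT", "A")
  variants$alt <- ifelse(is_indel, "A", "G")
  variants$transcript <- paste0("TX_", variants$gene)
  variants$vaf <- compute_vaf(variants$alt_depth, variants$depth)
  ccls <- classify_consequence(variants$hgvs_c, variants$hgvs_p,
                               variants$consequence_raw)
  variants <- bind_cols(variants, ccls)
  variants$variant_id <- paste(variants$chrom, variants$pos, variants$ref,
                               variants$alt, sep = ":")
  variants$class <- NULL

  # genotypes: every sampled member of the variant's family is typed
  fam_members <- members[c("family_id", "individual_id", "affection")]
  geno <- variants |>
    select("variant_id", "family_id", "carrier_id", "origin") |>
    left_join(fam_members, by = "family_id",
              relationship = "many-to-many") |>
    mutate(carrier = dplyr::case_when(
      .data$individual_id == .data$carrier_id ~ 1L,
      .data$origin == "causal" & .data$affection == "affected" ~ 1L,
      TRUE ~ 0L
    )) |>
    select("variant_id", "family_id", "individual_id", "carrier")

  manifest <- if (length(manifest)) bind_rows(manifest) else
    tibble(gene = character(), family_id = character(),
           class = character(), chip = logical())
  if (nrow(manifest)) {
    manifest$variant_id <- variants$variant_id[
      match(paste(manifest$gene, manifest$family_id),
            paste(variants$gene, variants$family_id))]
  } else {
    manifest$variant_id <- character(0)
  }
  gene_level <- manifest |>
    filter(!.data$chip) |>
    group_by(.data$gene) |>
    summarise(
      n_families = length(unique(.data$family_id)),
      n_lof = length(unique(.data$family_id[.data$class != "missense"])),
      n_missense = length(unique(.data$family_id[.data$class == "missense"])),
      .groups = "drop") |>
    mutate(expected_recoverable =
             .data$n_lof >= 2 |
             (.data$n_lof >= 1 & .data$n_families >= 2) |
             .data$n_missense >= 3)

  sim_id <- sprintf("famprio-sim-%d-%d", cfg$seed, cfg$n_families)
  attr(variants, "sim_id") <- sim_id
  attr(geno, "sim_id") <- sim_id
  attr(manifest, "sim_id") <- sim_id
  attr(manifest, "gene_level") <- gene_level
  structure(list(cohort = cohort, variants = variants, genotypes = geno,
                 manifest = manifest, config = cfg, sim_id = sim_id),
            class = "fam_simulation")
}

#' @export
print.fam_simulation <- function(x, ...) {
  cat(sprintf(
    "<fam_simulation> %s: %d families, %d variant rows (%d causal, %d CHIP)\n",
    x$sim_id, nrow(x$cohort$families), nrow(x$variants),
    sum(x$variants$origin == "causal"), sum(x$variants$origin == "chip")))
  invisible(x)
}

#' Construct a CHIP contaminant variant row
#'
#' Clonal hematopoiesis of indeterminate potential produces somatic clones
#' in blood-derived DNA that can mimic germline variants; the contaminant
#' is present in exactly one individual (never shared with relatives) with
#' a VAF anywhere in the clonal range, which may overlap the germline-range
#' threshold so that only recurrence and segregation can exclude it.
#'
#' @param individual_id,family_id the single carrier.
#' @param gene a CHIP-associated gene (TET2, DNMT3A, ASXL1).
#' @param vaf clonal allele fraction in `[0, 1]`.
#' @param depth read depth at the site.
#' @param .idx internal uniquifier for generated HGVS.
#' @return a one-row variant tibble (truncating change, `origin = "chip"`).
#' @export
inject_chip_contaminant <- function(individual_id, family_id,
                                    gene = c("TET2", "DNMT3A", "ASXL1"),
                                    vaf, depth = 80, .idx = 0) {
  gene <- match.arg(gene)
  stopifnot(vaf >= 0, vaf <= 1, depth >= 1)
  cls <- if (.idx %% 2 == 0) "nonsense" else "frameshift"
  h <- variant_hgvs(cls, .idx)
  alt <- max(round(vaf * depth), 1L)
  tibble(
    family_id = family_id, carrier_id = individual_id, gene = gene,
    class = cls, depth = as.integer(depth), alt_depth = as.integer(alt),
    exac_af = NA_real_, gnomad_af = NA_real_, segdup = FALSE,
    canonical = TRUE,
    polyphen2 = "missing", mutation_taster = "missing",
    sift = "missing", provean = "missing",
    hgvs_c = h$hgvs_c, hgvs_p = h$hgvs_p %||% NA_character_,
    consequence_raw = h$raw, origin = "chip"
  )
}

#' Evaluate recovery of injected signal from a discovery report
#'
#' Sensitivity is the fraction of manifest genes expected to be recoverable
#' (those whose injected variants meet the recurrence thresholds by
#' construction) that the pipeline included. A false inclusion is a gene
#' the pipeline included even though an independent recount of its passing
#' variants meets no recurrence threshold and it was not rescued — i.e. an
#' aggregation logic defect. Background genes that genuinely recur across
#' families by chance are legitimate inclusions under the published rule
#' and are reported separately as `n_background_recurrent`.
#'
#' @param report a `fam_discovery` from [run_discovery_pipeline()].
#' @param manifest the simulation manifest (same run).
#' @param config the [discovery_config()] used for the run.
#' @return list with `sensitivity` (`NA` when nothing was expected),
#'   `n_false_inclusions`, `n_background_recurrent`, `recovered`, `missed`,
#'   and a `per_gene` outcome table.
#' @export
evaluate_recovery <- function(report, manifest, config = discovery_config()) {
  stopifnot(inherits(report, "fam_discovery"))
  id_r <- attr(report, "sim_id", exact = TRUE)
  id_m <- attr(manifest, "sim_id", exact = TRUE)
  if (!is.null(id_r) && !is.null(id_m) && !identical(id_r, id_m)) {
    stop(sprintf("report (%s) and manifest (%s) come from different runs",
                 id_r, id_m), call. = FALSE)
  }
  gene_level <- attr(manifest, "gene_level", exact = TRUE)
  if (is.null(gene_level)) {
    gene_level <- manifest |>
      filter(!.data$chip) |>
      group_by(.data$gene) |>
      summarise(
        n_lof = length(unique(.data$family_id[.data$class != "missense"])),
        n_missense = length(unique(.data$family_id[.data$class == "missense"])),
        n_families = length(unique(.data$family_id)), .groups = "drop") |>
      mutate(expected_recoverable =
               .data$n_lof >= config$lof_family_min |
               (.data$n_lof >= 1 & .data$n_families >= config$mixed_family_min) |
               .data$n_missense >= config$missense_family_min)
  }
  expected <- gene_level$gene[gene_level$expected_recoverable]
  agg <- report$gene_aggregates
  included <- agg$gene[agg$included]

  # independent recount of the recurrence thresholds from the passing list
  p <- report$variants_passing
  recount_ok <- vapply(included, function(g) {
    rows <- p[p$gene == g, , drop = FALSE]
    f_lof <- unique(rows$family_id[rows$consequence != "missense"])
    f_mis <- unique(rows$family_id[rows$consequence == "missense"])
    length(f_lof) >= config$lof_family_min ||
      (length(f_lof) >= 1 &&
         length(union(f_lof, f_mis)) >= config$mixed_family_min) ||
      length(f_mis) >= config$missense_family_min
  }, logical(1))
  rescued <- agg$inclusion_reason[match(included, agg$gene)] ==
    "cross_reference_rescue"
  wrongly <- included[!recount_ok & !rescued]
  manifest_genes <- unique(manifest$gene)
  background_recurrent <- setdiff(included[recount_ok], manifest_genes)

  recovered <- intersect(expected, included)
  missed <- setdiff(expected, included)
  all_genes <- unique(c(expected, included))
  per_gene <- tibble(
    gene = all_genes,
    expected = all_genes %in% expected,
    included = all_genes %in% included
  )
  list(
    sensitivity = if (length(expected)) length(recovered) / length(expected)
    else NA_real_,
    n_false_inclusions = length(wrongly),
    false_inclusions = wrongly,
    n_background_recurrent = length(background_recurrent),
    recovered = recovered,
    missed = missed,
    per_gene = per_gene
  )
}

#' Write a simulation to disk in standard formats
#'
#' Produces a VCF (per-sample `GT:AD:DP`), the annotation TSV in the
#' [read_variants()] schema, a 6-column PED plus phenotype TSV, a wide
#' genotype matrix (variant x individual, 0/1/NA) and the manifest TSV —
#' everything needed to replay the simulation through the package's file
#' readers.
#'
#' @param sim a `fam_simulation`.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fam_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ped = file.path(dir, "cohort.ped"),
    pheno = file.path(dir, "phenotypes.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    anno = file.path(dir, "annotations.tsv"),
    geno = file.path(dir, "genotypes.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_cohort(sim$cohort, paths["ped"], paths["pheno"])

  v <- sim$variants
  uv <- v[!duplicated(v$variant_id), , drop = FALSE]
  uv <- uv[order(uv$chrom, uv$pos), , drop = FALSE]
  anno_cols <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
                 "canonical", "hgvs_c", "hgvs_p", "exac_af", "gnomad_af",
                 "segdup", PREDICTOR_COLS)
  anno <- uv[anno_cols]
  anno$consequence <- uv$consequence_raw
  readr::write_tsv(anno, paths["anno"], na = "")

  samples <- sim$cohort$members$individual_id[sim$cohort$members$sampled]
  g <- sim$genotypes
  gw <- tidyr::pivot_wider(g[c("variant_id", "individual_id", "carrier")],
                           names_from = "individual_id",
                           values_from = "carrier")
  readr::write_tsv(gw, paths["geno"], na = "NA")

  # VCF body: carrier rows use the simulated depths; genotyped relatives
  # get a synthesized AD consistent with their carrier status
  key <- paste(g$variant_id, g$individual_id)
  carrier_map <- setNames(g$carrier, key)
  vkey <- paste(v$variant_id, v$carrier_id)
  depth_map <- setNames(v$depth, vkey)
  altd_map <- setNames(v$alt_depth, vkey)
  body <- vapply(seq_len(nrow(uv)), function(i) {
    vid <- uv$variant_id[i]
    cells <- vapply(samples, function(s) {
      carr <- carrier_map[paste(vid, s)]
      if (is.na(carr)) return("./.:.:.")
      k <- paste(vid, s)
      if (carr == 1) {
        d <- depth_map[k]; a <- altd_map[k]
        if (is.na(d)) { d <- uv$depth[i]; a <- uv$alt_depth[i] }
        sprintf("0/1:%d,%d:%d", d - a, a, d)
      } else {
        sprintf("0/0:%d,0:%d", 50L, 50L)
      }
    }, character(1))
    paste(c(uv$chrom[i], uv$pos[i], vid, uv$ref[i], uv$alt[i], ".", "PASS",
            ".", "GT:AD:DP", cells), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), paths["vcf"])

  readr::write_tsv(sim$manifest, paths["manifest"], na = "")
  invisible(paths)
}
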