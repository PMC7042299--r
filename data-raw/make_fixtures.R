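# One-off deterministic generator for the packaged fixtures under
# inst/extdata. Run from the package root: Rscript data-raw/make_fixtures.R

dir.create("inst/extdata/external_lists", recursive = TRUE, showWarnings = FALSE)

## ---- known predisposition genes -------------------------------------------
known <- rbind(
  data.frame(gene = c("ANKRD26", "CEBPA", "DDX41", "ETV6", "GATA2", "RUNX1",
                      "TERC", "TERT", "TP53"),
             tier = "high", inheritance = "AD_het"),
  data.frame(gene = c("ACD", "CHEK2", "RTEL1", "SAMD9", "SAMD9L", "SRP72"),
             tier = "moderate", inheritance = "AD_het"),
  data.frame(gene = c("ATG2B/GSKIP", "MBD4", "MECOM"),
             tier = "emerging", inheritance = "AD_het"),
  data.frame(gene = c("ERCC6L2", "FANCA", "FANCC", "FANCG", "SBDS"),
             tier = "emerging", inheritance = "AR_biallelic"),
  data.frame(gene = "WAS", tier = "emerging", inheritance = "XL_hemizygous")
)
write.table(known, "inst/extdata/known_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## ---- established variants (previously described in familial MDS/AML) ------
kv <- data.frame(
  gene = c("CEBPA", "GATA2", "TERT", "FANCA", "SBDS", "SBDS"),
  hgvs_c = c("c.985_988dupGAAC", "c.1061C>T", "c.1445delA", "c.2505-1G>T",
             "c.258+2T>C", "c.183_184delinsCT"),
  hgvs_p = c("p.Gln330Argfs*74", "p.Thr354Met", "p.His482Profs*27", NA,
             NA, "p.Lys62X")
)
write.table(kv, "inst/extdata/known_variants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "")

## ---- RUNX1 deletions -------------------------------------------------------
del <- data.frame(
  label = c("FML029", "FML030", "FML031", "FML031"),
  chrom = "chr21",
  start = c(36349450, 36400658, 36389492, 36389457),
  end   = c(36572837, 36972948, 37056053, 37055677),
  set   = c("array", "array", "array", "report")
)
write.table(del, "inst/extdata/runx1_deletions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- synthetic RUNX1 feature model (BED, 0-based half-open) ---------------
# Illustrative layout: distal promoter and exons 1-2 inside the common
# deleted segment chr21:36400658-36572837; exon 3 outside it.
feat <- data.frame(
  chrom = "chr21",
  start0 = c(36560000, 36540000, 36480000, 36390000),
  end0   = c(36572000, 36541200, 36481100, 36391000),
  name = c("distal_promoter", "exon_1", "exon_2", "exon_3")
)
writeLines(sprintf("%s\t%d\t%d\t%s", feat$chrom, feat$start0, feat$end0,
                   feat$name),
           "inst/extdata/runx1_features_synthetic.bed")

## ---- external candidate lists ---------------------------------------------
writeLines(c("# candidate familial MDS/AML loci (illustrative subset)",
             "DNAH9"), "inst/extdata/external_lists/churpek.txt")
writeLines(c("# MDS/AML family candidate gene", "NAPRT1"),
           "inst/extdata/external_lists/patnaik.txt")
writeLines(c("# inherited BMF series: causal / likely causal / contributing",
             "SH2B3", "PRF1"), "inst/extdata/external_lists/bluteau.txt")

## ---- sporadic AML genes ----------------------------------------------------
writeLines(c(
  "# genes reported mutated in sporadic AML (TCGA-LAML / BeatAML)",
  "FLT3", "NPM1", "DNMT3A", "IDH1", "IDH2", "TET2", "RUNX1", "TP53", "NRAS",
  "KRAS", "CEBPA", "WT1", "PTPN11", "KIT", "U2AF1", "SMC1A", "SMC3", "RAD21",
  "STAG2", "PHF6", "ASXL1", "EZH2", "SRSF2", "SF3B1", "ZRSR2", "BCOR",
  "GATA2", "JAK2", "CALR", "MPL", "CSF3R", "SETBP1", "ETV6", "IKZF1", "GNAS",
  "MYC"), "inst/extdata/sporadic_aml_genes.txt")

## ---- 86-family example cohort ---------------------------------------------
# Totals: 86 families, 221 individuals, 168 affected, 53 unaffected.
# Categories: MDS 12, AML 17, MDS/AML 18, MDS/AML/TCP 15, MDS/AML/BMF 24.
ped <- list(); pheno <- list()
fam_i <- 0
add_family <- function(diags, unaffected = 0, extra = character(0)) {
  fam_i <<- fam_i + 1
  fid <- sprintf("FML%03d", fam_i)
  diags <- c(diags, extra)
  n_aff <- length(diags)
  ids <- sprintf("II.%d", seq_len(n_aff + unaffected))
  aff <- c(rep(2, n_aff), rep(1, unaffected))
  sex <- rep(c(1, 2), length.out = length(ids))
  ped[[length(ped) + 1]] <<- data.frame(
    fid = fid, iid = ids, pat = 0, mat = 0, sex = sex, pheno = aff)
  pheno[[length(pheno) + 1]] <<- data.frame(
    family_id = fid, individual_id = ids,
    diagnosis = c(diags, rep("none", unaffected)),
    age_at_onset = c(20 + 3 * seq_len(n_aff), rep(NA, unaffected)),
    index_case = seq_along(ids) == 1,
    sampled = TRUE)
}
for (i in 1:12) add_family("MDS")                                   # MDS
for (i in 1:17) add_family("AML")                                   # AML
for (i in 1:18) add_family(c("MDS", "AML"), unaffected = 1)         # MDS/AML
add_family(c("MDS", "TCP", "MDS"), unaffected = 1)                  # TCP +1 extra
for (i in 2:15) add_family(c("AML", "TCP"), unaffected = 1)         # TCP
for (i in 1:20) add_family(c("AML", "BMF", "MDS"), unaffected = 1)  # BMF (+extra)
for (i in 21:24) add_family(c("MDS", "BMF", "AML"))                 # BMF, no unaff
ped <- do.call(rbind, ped); pheno <- do.call(rbind, pheno)
stopifnot(nrow(ped) == 221,
          sum(ped$pheno == 2) == 168,
          sum(ped$pheno == 1) == 53,
          length(unique(ped$fid)) == 86)
write.table(ped, "inst/extdata/familial_cohort.ped", sep = " ",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(pheno, "inst/extdata/familial_cohort_phenotypes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")

## ---- per-family known-locus calls (group assignment fixture) ---------------
# 49 explained families (39 high / 4 moderate / 6 emerging), 37 unexplained.
high <- c(RUNX1 = 8, GATA2 = 7, CEBPA = 6, DDX41 = 5, TERT = 5, TERC = 3,
          ETV6 = 2, ANKRD26 = 2, TP53 = 1)
moderate <- c(SAMD9L = 1, SRP72 = 1, ACD = 1, CHEK2 = 1)
emerging <- c("ATG2B/GSKIP" = 1, ERCC6L2 = 1, FANCA = 1, MECOM = 1,
              SBDS = 1, WAS = 1)
stopifnot(sum(high) == 39, sum(moderate) == 4, sum(emerging) == 6)
genes <- c(rep(names(high), high), rep(names(moderate), moderate),
           rep(names(emerging), emerging))
tiers <- c(rep("high", 39), rep("moderate", 4), rep("emerging", 6))
cats <- rep(c("pathogenic", "likely_pathogenic"), length.out = 49)
calls <- data.frame(
  family_id = sprintf("FML%03d", 1:86),
  gene = c(genes, rep(NA, 37)),
  tier = c(tiers, rep(NA, 37)),
  category = c(cats, rep("none", 37))
)
write.table(calls, "inst/extdata/known_locus_families.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")

cat("fixtures written\n")
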