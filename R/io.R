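#' @include AllClasses.R
NULL

## Constructors ------------------------------------------------------------

#' Construct a HaplotypePanel
#'
#' @param variants data.frame with columns id, chrom, pos, a1, a2 and
#'   optionally risk (filled with NA when absent).
#' @param haplotypes character allele matrix, 2 rows per sample.
#' @param sampleIds sample identifiers; defaults to S1..Sn.
#' @param ancestry ancestry label.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
HaplotypePanel <- function(variants, haplotypes, sampleIds = NULL,
                           ancestry = "unknown") {
  if (!"risk" %in% names(variants)) variants$risk <- NA_character_
  variants$pos <- as.integer(variants$pos)
  haplotypes <- as.matrix(haplotypes)
  dimnames(haplotypes) <- NULL
  if (is.null(sampleIds))
    sampleIds <- paste0("S", seq_len(nrow(haplotypes) / 2))
  new("HaplotypePanel", variants = as.data.frame(variants),
      haplotypes = haplotypes, sampleIds = as.character(sampleIds),
      ancestry = ancestry)
}

#' Construct a GenotypeMatrix
#'
#' @param variants data.frame with columns id, chrom, pos, a1, a2,
#'   optionally risk and counted.  When \code{counted} is absent it is the
#'   risk allele where declared, otherwise the alphabetically first allele.
#' @param genotypes integer dosage matrix (0/1/2/NA), samples x variants.
#' @param sampleIds sample identifiers.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(variants, genotypes, sampleIds) {
  if (!"risk" %in% names(variants)) variants$risk <- NA_character_
  if (!"counted" %in% names(variants))
    variants$counted <- ifelse(!is.na(variants$risk), variants$risk,
                               pmin(variants$a1, variants$a2))
  variants$pos <- as.integer(variants$pos)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- NULL
  new("GenotypeMatrix", variants = as.data.frame(variants),
      genotypes = genotypes, sampleIds = as.character(sampleIds))
}

#' Construct a CaseControlStudy
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param phenotypes data.frame with sampleId, status, cohort.
#' @param cohort cohort label (defaults to the phenotype table's label).
#' @param lambda genomic-control inflation factor; values below 1 trigger
#'   a warning (deflation below the null is not expected).
#' @return A \linkS4class{CaseControlStudy}.
#' @export
CaseControlStudy <- function(genotypes, phenotypes, cohort = NULL,
                             lambda = 1.0) {
  phenotypes <- as.data.frame(phenotypes)
  if (is.null(cohort)) cohort <- as.character(phenotypes$cohort[1])
  idx <- match(genotypes@sampleIds, phenotypes$sampleId)
  if (anyNA(idx)) stop("every genotyped sample needs a phenotype row")
  phenotypes <- phenotypes[idx, , drop = FALSE]
  rownames(phenotypes) <- NULL
  if (lambda < 1) warning("inflation factor lambda < 1")
  new("CaseControlStudy", genotypes = genotypes, phenotypes = phenotypes,
      cohort = cohort, lambda = lambda)
}

## Internal VCF helpers ----------------------------------------------------

.vcf_gt_field <- function(gt) sub(":.*$", "", gt)

.read_vcf_calls <- function(path, phased) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp))
    warning(sum(!snp), " multi-allelic or non-SNP record(s) skipped: ",
            paste(utils::head(fix[!snp, "ID"], 3), collapse = ", "))
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcf@gt[snp, -1, drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ref <- ref[snp]; alt <- alt[snp]
  calls <- apply(gt, 2, .vcf_gt_field)
  if (is.null(dim(calls)))
    calls <- matrix(calls, nrow = nrow(fix), dimnames = dimnames(gt))
  if (phased) {
    unph <- grepl("/", calls) & calls != "./."
    if (any(unph)) {
      i <- which(unph, arr.ind = TRUE)[1, 1]
      stop("unphased genotype at record ", fix[i, "ID"],
           "; phased panels require '|' separators")
    }
  }
  list(
    variants = data.frame(
      id = fix[, "ID"], chrom = fix[, "CHROM"],
      pos = as.integer(fix[, "POS"]), a1 = ref, a2 = alt,
      risk = NA_character_, stringsAsFactors = FALSE),
    calls = calls,
    samples = colnames(vcf@gt)[-1]
  )
}

## Readers -----------------------------------------------------------------

#' Read a phased haplotype reference panel
#'
#' Accepts a VCF with phased GT fields (two haplotype rows per sample) or
#' an allele-matrix TSV in the panel dialect: one row per chromosome, one
#' column per SNP, single-letter alleles, \code{NA} for missing, an
#' optional leading \code{sample} column naming the chromosome's sample.
#' Multi-allelic and non-SNP VCF records are skipped with a warning.
#'
#' @param path path to the panel file.
#' @param ancestry ancestry label attached to the panel.
#' @param format "vcf", "tsv" or "auto" (by extension).
#' @param risk optional named character vector mapping SNP id to its
#'   at-risk allele.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
readPhasedPanel <- function(path, ancestry = "unknown",
                            format = c("auto", "vcf", "tsv"), risk = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    x <- .read_vcf_calls(path, phased = TRUE)
    v <- x$variants
    alle <- strsplit(gsub("[|]", "", x$calls), "")
    ## calls is records x samples; build 2 rows per sample
    n <- length(x$samples); m <- nrow(v)
    hap <- matrix(NA_character_, 2L * n, m)
    for (j in seq_len(n)) {
      for (i in seq_len(m)) {
        g <- strsplit(x$calls[i, j], "\\|")[[1]]
        if (length(g) != 2L || any(g == ".")) next
        hap[2L * j - 1L, i] <- c(v$a1[i], v$a2[i])[as.integer(g[1]) + 1L]
        hap[2L * j, i]      <- c(v$a1[i], v$a2[i])[as.integer(g[2]) + 1L]
      }
    }
    samples <- x$samples
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             na.strings = "NA")
    if (nrow(tab) == 0L) stop("empty panel file: ", path)
    if (names(tab)[1] == "sample") {
      ids <- tab$sample
      tab <- tab[, -1, drop = FALSE]
      samples <- unique(ids)
      if (nrow(tab) != 2L * length(samples))
        stop("panel TSV must carry two chromosome rows per sample")
    } else {
      if (nrow(tab) %% 2L != 0L)
        stop("panel TSV must have an even number of chromosome rows")
      samples <- paste0("S", seq_len(nrow(tab) / 2))
    }
    hap <- as.matrix(tab)
    v <- .infer_variants(colnames(tab), hap)
    dimnames(hap) <- NULL
  }
  if (!is.null(risk)) {
    hit <- match(v$id, names(risk))
    v$risk <- ifelse(is.na(hit), v$risk, unname(risk)[hit])
  }
  HaplotypePanel(v, hap, samples, ancestry)
}

## Allele metadata from observed data when no VCF header is available;
## positions fall back to column order.
.infer_variants <- function(ids, allele_matrix) {
  m <- ncol(allele_matrix)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    obs <- sort(unique(allele_matrix[, j]))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2L)
      stop("more than two alleles observed at ", ids[j])
    a1[j] <- obs[1]
    a2[j] <- if (length(obs) == 2L) obs[2] else setdiff(c("A", "C", "G", "T"), obs)[1]
  }
  data.frame(id = ids, chrom = "un", pos = seq_len(m), a1 = a1, a2 = a2,
             risk = NA_character_, stringsAsFactors = FALSE)
}

#' Read a case-control study
#'
#' Genotypes come from a VCF (unphased GT) or a genotype TSV: first column
#' \code{sampleId}, one column per SNP, cells like \code{"A/G"} with
#' \code{NA} for missing.  Phenotypes come from a TSV with columns
#' \code{sampleId}, \code{status} (case/control) and \code{cohort}.
#' Genotyped samples without a phenotype row are dropped with a message;
#' the counted allele per variant is the declared risk allele where given,
#' otherwise the alternate (VCF) or alphabetically first (TSV) allele.
#'
#' @param genotypePath VCF or genotype TSV.
#' @param phenotypePath phenotype TSV.
#' @param cohort cohort label; defaults to the phenotype table's value.
#' @param lambda genomic-control inflation factor (default 1).
#' @param risk optional named character vector of at-risk alleles by SNP.
#' @param format genotype file format ("auto", "vcf", "tsv").
#' @return A \linkS4class{CaseControlStudy}.
#' @export
readStudy <- function(genotypePath, phenotypePath, cohort = NULL,
                      lambda = 1.0, risk = NULL,
                      format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", genotypePath)) "vcf" else "tsv"
  if (format == "vcf") {
    x <- .read_vcf_calls(genotypePath, phased = FALSE)
    v <- x$variants
    samples <- x$samples
    gt <- matrix(NA_integer_, length(samples), nrow(v))
    for (i in seq_len(nrow(v))) {
      g <- x$calls[i, ]
      g <- gsub("\\|", "/", g)
      gt[, i] <- ifelse(g %in% c("./.", "."), NA_integer_,
                        as.integer(substr(g, 1, 1) == "1") +
                        as.integer(substr(g, 3, 3) == "1"))
    }
    counted_default <- v$a2   # dosage above counts the ALT allele
  } else {
    tab <- utils::read.table(genotypePath, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             na.strings = "NA")
    if (names(tab)[1] != "sampleId") stop("genotype TSV needs a sampleId column")
    samples <- tab$sampleId
    cells <- as.matrix(tab[, -1, drop = FALSE])
    pair <- gsub("/", "", cells)
    v <- .infer_variants(colnames(cells),
                         rbind(substr(pair, 1, 1), substr(pair, 2, 2)))
    counted_default <- pmin(v$a1, v$a2)
    gt <- matrix(NA_integer_, length(samples), nrow(v))
    for (i in seq_len(nrow(v)))
      gt[, i] <- ifelse(is.na(pair[, i]), NA_integer_,
                        (substr(pair[, i], 1, 1) == counted_default[i]) +
                        (substr(pair[, i], 2, 2) == counted_default[i]))
  }
  if (!is.null(risk)) {
    hit <- match(v$id, names(risk))
    v$risk <- ifelse(is.na(hit), v$risk, unname(risk)[hit])
  }
  v$counted <- counted_default
  flip <- !is.na(v$risk) & v$risk != v$counted
  if (any(flip)) {           # re-orient dosages onto the declared risk allele
    gt[, flip] <- 2L - gt[, flip]
    v$counted[flip] <- v$risk[flip]
  }

  ph <- utils::read.table(phenotypePath, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("sampleId", "status", "cohort") %in% names(ph)))
    stop("phenotype TSV needs columns sampleId, status, cohort")
  bad <- setdiff(unique(ph$status), c("case", "control"))
  if (length(bad))
    stop("invalid status code(s) ", paste(bad, collapse = ", "),
         "; allowed codes are 'case' and 'control'")
  keep <- samples %in% ph$sampleId
  if (!any(keep)) stop("no overlapping samples between genotype and phenotype files")
  if (any(!keep))
    message(sum(!keep), " genotyped sample(s) without phenotype dropped")
  gm <- GenotypeMatrix(v, gt[keep, , drop = FALSE], samples[keep])
  CaseControlStudy(gm, ph, cohort = cohort, lambda = lambda)
}

#' Read a trio pedigree
#'
#' Three-column TSV (child, father, mother).  Duplicate triples collapse
#' to one; a triple with repeated ids is rejected.
#'
#' @param path pedigree TSV path.
#' @return data.frame with columns child, father, mother.
#' @export
readPedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pedigree file: ", path)
  parts <- strsplit(lines, "\t")
  if (identical(tolower(trimws(parts[[1]])), c("child", "father", "mother"))) {
    parts <- parts[-1]
    off <- 1L
  } else off <- 0L
  bad <- which(vapply(parts, length, 0L) != 3L)
  if (length(bad))
    stop("malformed pedigree row at line ", bad[1] + off, " (need 3 columns)")
  ped <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(ped) <- c("child", "father", "mother")
  dup_id <- apply(ped, 1, function(r) anyDuplicated(r) > 0)
  if (any(dup_id))
    stop("pedigree line ", which(dup_id)[1] + off,
         ": child, father and mother ids must be distinct")
  ped <- unique(ped)
  rownames(ped) <- NULL
  ped
}

## Writers -----------------------------------------------------------------

#' Write a stage result table
#'
#' Serializes any stage's result data.frame as TSV or JSON with a
#' deterministic column order and numbers at 6 significant digits, so the
#' two renderings parse back to the same values.
#'
#' @param results a data.frame.
#' @param path output path.
#' @param format "tsv" or "json".
#' @export
writeResults <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  num <- vapply(results, is.numeric, TRUE)
  results[num] <- lapply(results[num], signif, digits = 6)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(results, path, digits = NA, na = "null",
                         auto_unbox = FALSE)
  }
  invisible(path)
}

#' Write a haplotype panel as TSV (round-trip partner of readPhasedPanel)
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param path output path.
#' @export
writePanel <- function(panel, path) {
  h <- panel@haplotypes
  out <- data.frame(sample = rep(panel@sampleIds, each = 2),
                    as.data.frame(h), check.names = FALSE)
  names(out)[-1] <- panel@variants$id
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a case-control study as a genotype TSV plus a phenotype TSV
#' @param study a \linkS4class{CaseControlStudy}.
#' @param genotypePath,phenotypePath output paths.
#' @export
writeStudy <- function(study, genotypePath, phenotypePath) {
  gm <- study@genotypes
  v <- gm@variants
  g <- gm@genotypes
  cells <- matrix(NA_character_, nrow(g), ncol(g))
  for (i in seq_len(ncol(g))) {
    other <- if (v$counted[i] == v$a1[i]) v$a2[i] else v$a1[i]
    ## alphabetically sorted unordered pairs per dosage
    strings <- c(paste0(other, "/", other),
                 paste0(min(v$counted[i], other), "/",
                        max(v$counted[i], other)),
                 paste0(v$counted[i], "/", v$counted[i]))
    ok <- !is.na(g[, i])
    cells[ok, i] <- strings[g[ok, i] + 1L]
  }
  out <- data.frame(sampleId = gm@sampleIds, as.data.frame(cells),
                    check.names = FALSE)
  names(out)[-1] <- v$id
  utils::write.table(out, genotypePath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(study@phenotypes, phenotypePath, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(genotypePath)
}

#' Write a trio pedigree TSV
#' @param pedigree data.frame with child, father, mother.
#' @param path output path.
#' @export
writePedigree <- function(pedigree, path) {
  utils::write.table(pedigree[c("child", "father", "mother")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
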