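#' @include AllClasses.R ld.R assoc.R meta.R hapfreq.R
NULL

#' Run the ancestry-shift refinement workflow end to end
#'
#' Orchestrates the stages in order: index-SNP screening on the
#' screening panel, per-ancestry equivalence classes and tag choice,
#' per-cohort allelic association with likelihood recovery of missing
#' genotypes (so the same individuals support every SNP within a
#' cohort), cross-cohort Mantel-Haenszel combination with heterogeneity,
#' a conditional matrix around the top combined SNP, and a per-cohort
#' haplotype frequency table.  SNPs selected in screening but untyped in
#' a cohort are flagged rather than silently dropped.
#'
#' @param panels named list of \linkS4class{HaplotypePanel} objects (one
#'   per ancestry); the first is the screening panel unless
#'   \code{screenAncestry} names another.
#' @param studies named list of \linkS4class{CaseControlStudy} objects.
#' @param indexSnp id of the index SNP for screening.
#' @param r2Select screening threshold (default 0.65).
#' @param r2Class equivalence-class threshold (default 0.8).
#' @param alpha family-wise error rate for the class-level Bonferroni
#'   threshold (default 0.05).
#' @param screenAncestry name of the panel used for screening.
#' @param outDir optional directory; when given, every stage's table is
#'   written there as TSV.
#' @return list (report bundle) with elements \code{selected},
#'   \code{classes}, \code{association}, \code{meta}, \code{conditional},
#'   \code{haplotypes}, \code{threshold}, \code{topSnp}, \code{log}.
#' @export
runPipeline <- function(panels, studies, indexSnp,
                        r2Select = 0.65, r2Class = 0.8, alpha = 0.05,
                        screenAncestry = names(panels)[1], outDir = NULL) {
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## 1. screening on the designated panel
  screen_panel <- panels[[screenAncestry]]
  ld_screen <- stage("screen", pairwiseLD(screen_panel))
  pos <- stats::setNames(screen_panel@variants$pos, screen_panel@variants$id)
  selected <- stage("screen",
                    selectCorrelated(ld_screen, indexSnp, r2Select, pos))
  note("screen: %d SNPs at r2 >= %.3g with %s in %s",
       length(selected), r2Select, indexSnp, screenAncestry)

  ## 2-3. classes and tags per ancestry panel
  classes <- lapply(names(panels), function(anc) {
    p <- panels[[anc]]
    snps <- intersect(selected, p@variants$id)
    ld <- pairwiseLD(p, snps)
    cl <- clusterClasses(ld, snps, r2Class, ancestry = anc)
    chooseTags(cl, ld, positions = pos)
  })
  names(classes) <- names(panels)
  screen_classes <- classes[[screenAncestry]]
  threshold <- bonferroniThreshold(alpha, screen_classes)
  note("classes: %d in %s; class-level threshold %.4g",
       length(screen_classes@classes), screenAncestry, threshold)

  ## 4. per-cohort association with imputation
  assoc_rows <- list()
  imputed_store <- list()
  for (cn in names(studies)) {
    st <- studies[[cn]]
    typed <- intersect(selected, st@genotypes@variants$id)
    untyped <- setdiff(selected, typed)
    imputed_store[[cn]] <- list()
    for (s in selected) {
      if (s %in% untyped) {
        assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
          snp = s, allele = NA_character_, cohort = cn,
          freq_controls = NA_real_, OR = NA_real_, CI_low = NA_real_,
          CI_high = NA_real_, P = NA_real_, chi2 = NA_real_,
          model = "untyped", stringsAsFactors = FALSE)
        next
      }
      imp <- stage("assoc", {
        i <- match(s, st@genotypes@variants$id)
        if (anyNA(st@genotypes@genotypes[, i]))
          imputeMissing(st, s, setdiff(typed, s))
        else stats::setNames(numeric(0), character(0))
      })
      imputed_store[[cn]][[s]] <- imp
      assoc_rows[[length(assoc_rows) + 1L]] <-
        stage("assoc", allelicAssociation(st, s, imputed = imp))
    }
    note("assoc[%s]: %d typed, %d untyped SNPs", cn, length(typed),
         length(untyped))
  }
  association <- do.call(rbind, assoc_rows)
  rownames(association) <- NULL

  ## 5. cross-cohort meta + heterogeneity per SNP
  meta_rows <- lapply(selected, function(s) {
    tabs <- list(); lams <- numeric()
    for (cn in names(studies)) {
      st <- studies[[cn]]
      if (!s %in% st@genotypes@variants$id) next
      tabs[[cn]] <- alleleCountTable(st, s, imputed = imputed_store[[cn]][[s]])
      lams <- c(lams, st@lambda)
    }
    if (!length(tabs))
      return(data.frame(snp = s, OR = NA_real_, CI_low = NA_real_,
                        CI_high = NA_real_, P = NA_real_, Q = NA_real_,
                        P_het = NA_real_, I2 = NA_real_, k = 0L))
    mr <- stage("meta", mantelHaenszel(tabs, lams))
    data.frame(snp = s, OR = mr@or, CI_low = mr@ciLow, CI_high = mr@ciHigh,
               P = mr@p, Q = mr@q, P_het = mr@pHet, I2 = mr@i2, k = mr@k,
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL

  ## 6. conditional matrix around the top combined SNP
  ok <- !is.na(meta$P)
  topSnp <- meta$snp[ok][which.min(meta$P[ok])]
  note("meta: top combined SNP %s (P = %.3g)", topSnp,
       min(meta$P[ok]))
  cond_rows <- list()
  for (cn in names(studies)) {
    st <- studies[[cn]]
    typed <- intersect(selected, st@genotypes@variants$id)
    if (!topSnp %in% typed) next
    for (s in setdiff(typed, topSnp)) {
      imp <- list(primary = imputed_store[[cn]][[s]],
                  adjust = imputed_store[[cn]][[topSnp]])
      row <- tryCatch(
        conditionalAssociation(st, s, topSnp, imputed = imp),
        error = function(e) {
          note("conditional[%s] %s|%s skipped: %s", cn, s, topSnp,
               conditionMessage(e))
          NULL
        })
      if (!is.null(row)) cond_rows[[length(cond_rows) + 1L]] <- row
    }
  }
  conditional <- if (length(cond_rows)) do.call(rbind, cond_rows) else
    data.frame(primary_snp = character(), adjust_snp = character(),
               cohort = character(), OR_adj = numeric(), CI_low = numeric(),
               CI_high = numeric(), P_residual = numeric(), n = integer())
  rownames(conditional) <- NULL

  ## 7. haplotype frequency table per cohort
  hap_tabs <- lapply(names(studies), function(cn) {
    st <- studies[[cn]]
    typed <- intersect(selected, st@genotypes@variants$id)
    if (length(typed) < 2L || length(typed) > 12L) return(NULL)
    idx <- match(typed, st@genotypes@variants$id)
    ft <- stage("haplo", emHaplotypeFrequencies(
      .subsetGenotypes(st@genotypes, idx), groups = st@phenotypes$status))
    fr <- hapFrequencies(ft)
    data.frame(cohort = cn, haplotype = rownames(fr),
               as.data.frame(fr), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  haplotypes <- do.call(rbind, hap_tabs)

  bundle <- list(selected = selected, classes = classes,
                 association = association, meta = meta,
                 conditional = conditional, haplotypes = haplotypes,
                 threshold = threshold, topSnp = topSnp, log = log_lines)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeResults(association, file.path(outDir, "association.tsv"))
    writeResults(meta, file.path(outDir, "meta.tsv"))
    writeResults(conditional, file.path(outDir, "conditional.tsv"))
    if (!is.null(haplotypes))
      writeResults(haplotypes, file.path(outDir, "haplotypes.tsv"))
    class_tab <- do.call(rbind, lapply(names(classes), function(anc)
      data.frame(ancestry = anc,
                 class = rep(names(classes[[anc]]@classes),
                             lengths(classes[[anc]]@classes)),
                 snp = unlist(classes[[anc]]@classes, use.names = FALSE),
                 stringsAsFactors = FALSE)))
    writeResults(class_tab, file.path(outDir, "classes.tsv"))
    writeLines(log_lines, file.path(outDir, "run.log"))
  }
  bundle
}
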