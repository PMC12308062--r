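#' Triage thresholds
#'
#' Variants are excluded when their deleteriousness (CADD) score is
#' strictly below \code{caddMin}, or their population minor allele
#' frequency exceeds \code{mafBiallelicMax} in a biallelic genotype
#' context or \code{mafMonoallelicMax} in a monoallelic (or hemizygous)
#' context. A missing frequency is treated as 0; a missing CADD score
#' passes the CADD test (several retained truncating variants carry no
#' score).
#'
#' @param caddMin CADD exclusion threshold (exclude when strictly below);
#'   default 15.
#' @param mafBiallelicMax Frequency ceiling for biallelic contexts;
#'   default 0.01.
#' @param mafMonoallelicMax Frequency ceiling for monoallelic and
#'   hemizygous contexts; default 0.001.
#' @param depthThreshold Reporting depth threshold carried alongside;
#'   default 20.
#' @return List of class \code{"TriageParams"}.
#' @export
triageParams <- function(caddMin = 15, mafBiallelicMax = 0.01,
                         mafMonoallelicMax = 0.001, depthThreshold = 20L) {
  stopifnot(mafMonoallelicMax > 0,
            mafMonoallelicMax <= mafBiallelicMax)
  structure(list(caddMin = caddMin, mafBiallelicMax = mafBiallelicMax,
                 mafMonoallelicMax = mafMonoallelicMax,
                 depthThreshold = depthThreshold),
            class = "TriageParams")
}

#' Classify a variant's consequence from HGVS nomenclature
#'
#' Deterministic precedence: structural (whole-exon events) >
#' frameshift (protein carries an \code{fs} designation) > nonsense
#' (substitution to a stop without frameshift) > splice (cDNA position
#' with an intronic offset, or unknown protein \code{p.?} with an
#' offset-bearing cDNA change) > missense (single-residue substitution) >
#' other. Unparseable nomenclature falls through to \code{other}.
#'
#' @param cdna HGVS cDNA strings (e.g. \code{"c.954-2A>T"}).
#' @param protein HGVS protein strings (e.g. \code{"p.(Gln452*)"}).
#' @param structural Logical, whole-exon structural records.
#' @return Character vector over \{missense, nonsense, frameshift,
#'   splice, large_deletion, other\}; exactly one class per variant.
#' @examples
#' classifyConsequence("c.2912del", "p.(Pro971Glnfs*95)")  # frameshift
#' classifyConsequence("c.954-2A>T", "p.?")                # splice
#' @export
classifyConsequence <- function(cdna, protein,
                                structural = FALSE) {
  n <- max(length(cdna), length(protein), length(structural))
  cdna <- rep_len(ifelse(is.na(cdna), "", cdna), n)
  protein <- rep_len(ifelse(is.na(protein), "", protein), n)
  structural <- rep_len(structural, n)
  protein <- gsub("∗", "*", protein)  # normalise unicode asterisk
  out <- character(n)
  isFrameshift <- grepl("fs", protein, fixed = TRUE)
  isNonsense <- grepl("^p\\.\\(?[A-Za-z]{3}[0-9]+(\\*|Ter)\\)?$", protein)
  spliceOffset <- grepl("c\\.[0-9]+[+-][0-9]+", cdna)
  unknownProt <- protein %in% c("", "p.?")
  isMissense <- grepl("^p\\.\\(?[A-Za-z]{3}[0-9]+[A-Za-z]{3}\\)?$",
                      protein) & !isFrameshift
  for (i in seq_len(n)) {
    out[i] <- if (isTRUE(structural[i])) "large_deletion"
      else if (isFrameshift[i]) "frameshift"
      else if (isNonsense[i]) "nonsense"
      else if (spliceOffset[i] && unknownProt[i]) "splice"
      else if (isMissense[i]) "missense"
      else "other"
  }
  out
}

#' Apply the CADD / allele-frequency filter to one or more variants
#'
#' Exclusion is strict: a present CADD score below the threshold, or a
#' frequency strictly above the ceiling for the variant's genotype
#' context (\code{"biallelic"}: homozygous or compound-heterozygous
#' member; \code{"monoallelic"}: lone heterozygous; \code{"hemizygous"}:
#' single-copy chrX, which uses the monoallelic ceiling). Each excluded
#' variant carries exactly one first-failing rule; the CADD rule is
#' evaluated first.
#'
#' @param cadd Numeric CADD scores (NA = unscored, passes).
#' @param af Numeric population frequencies (NA = absent, treated as 0).
#' @param context Character vector over \{biallelic, monoallelic,
#'   hemizygous\}.
#' @param params \code{\link{triageParams}}.
#' @return data.frame with \code{keep} (logical) and \code{rule}
#'   (\code{"pass"}, \code{"cadd_below_min"}, \code{"af_above_biallelic"}
#'   or \code{"af_above_monoallelic"}).
#' @examples
#' frequencyCaddFilter(40, 0.0024, "monoallelic")  # excluded
#' frequencyCaddFilter(25, 0.0011, "biallelic")    # kept
#' @export
frequencyCaddFilter <- function(cadd, af, context,
                                params = triageParams()) {
  n <- max(length(cadd), length(af), length(context))
  cadd <- rep_len(cadd, n); af <- rep_len(af, n)
  context <- rep_len(context, n)
  stopifnot(all(context %in% c("biallelic", "monoallelic", "hemizygous")))
  af0 <- ifelse(is.na(af), 0, af)
  rule <- rep("pass", n)
  caddFail <- !is.na(cadd) & cadd < params$caddMin
  rule[caddFail] <- "cadd_below_min"
  biall <- context == "biallelic"
  afFail <- !caddFail &
    ((biall & af0 > params$mafBiallelicMax) |
       (!biall & af0 > params$mafMonoallelicMax))
  rule[afFail & biall] <- "af_above_biallelic"
  rule[afFail & !biall] <- "af_above_monoallelic"
  data.frame(keep = rule == "pass", rule = rule,
             stringsAsFactors = FALSE)
}

#' Load the packaged gene-specific rule table
#'
#' Currently one rule: truncating (nonsense or frameshift) FAM83H
#' variants qualify for a diagnosis only inside the gene's large last
#' coding exon; the packaged interval is an approximation of that exon
#' (0-based half-open).
#'
#' @return data.frame with \code{gene}, \code{rule}, \code{contig},
#'   \code{start}, \code{end}, \code{note}.
#' @export
loadGeneRules <- function() {
  tab <- read.delim(.extdata("gene_rules.tsv"), colClasses = "character")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab
}

# 1-based genomic position from an HGVS-like genomic key; NA when the
# key is not positional (e.g. structural labels)
.genomicPos <- function(genomic) {
  m <- regmatches(genomic, regexec("^(chr[0-9XYM]+):g\\.?([0-9]+)",
                                   genomic))
  vapply(m, function(x) if (length(x) == 3L) as.integer(x[3L]) else
    NA_integer_, integer(1))
}

.genomicContig <- function(genomic) {
  m <- regmatches(genomic, regexec("^(chr[0-9XYM]+):", genomic))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Apply gene-specific qualification rules
#'
#' Truncating variants in a gene with a \code{truncating_last_exon_only}
#' rule are flagged \code{gene_rule_failed} when they fall outside the
#' configured last-exon interval, and do not count towards diagnoses.
#' All other variants pass unchanged.
#'
#' @param gene Gene symbols.
#' @param genomic Genomic keys (e.g. \code{"chr8:g.144810257G>T"}).
#' @param consequence Classes from \code{\link{classifyConsequence}}.
#' @param rules Rule table from \code{\link{loadGeneRules}}.
#' @return data.frame with \code{keep} and \code{rule} (\code{"pass"} or
#'   \code{"gene_rule_failed"}).
#' @export
applyGeneRules <- function(gene, genomic, consequence,
                           rules = loadGeneRules()) {
  n <- max(length(gene), length(genomic), length(consequence))
  gene <- rep_len(gene, n); genomic <- rep_len(genomic, n)
  consequence <- rep_len(consequence, n)
  keep <- rep(TRUE, n)
  pos <- .genomicPos(genomic)
  for (r in seq_len(nrow(rules))) {
    if (rules$rule[r] != "truncating_last_exon_only") next
    hit <- gene == rules$gene[r] &
      consequence %in% c("nonsense", "frameshift") &
      !is.na(pos) &
      !(pos > rules$start[r] & pos <= rules$end[r])
    keep[hit] <- FALSE
  }
  data.frame(keep = keep,
             rule = ifelse(keep, "pass", "gene_rule_failed"),
             stringsAsFactors = FALSE)
}

# genotype context of each variant row within its (family, gene) group
.zygosityContext <- function(family, gene, zygosity) {
  key <- paste(family, gene, sep = "\r")
  nInGroup <- stats::ave(seq_along(key), key, FUN = length)
  ifelse(zygosity == "hom", "biallelic",
         ifelse(zygosity == "hemi", "hemizygous",
                ifelse(nInGroup >= 2L, "biallelic", "monoallelic")))
}

#' Run the full triage cascade over a variant table
#'
#' Classifies consequences, derives each variant's genotype context from
#' its (family, gene) group (homozygous or member of a multi-variant
#' group: biallelic; lone heterozygous: monoallelic; hemizygous:
#' monoallelic ceiling), applies the CADD/frequency filter and the
#' gene-specific rules, and records one first-failing rule per excluded
#' variant. Context is fixed by the input genotypes, making the cascade
#' idempotent and order-independent across its rules.
#'
#' @param variants data.frame with columns \code{family}, \code{gene},
#'   \code{genomic}, \code{cdna}, \code{protein}, \code{zygosity}
#'   (het/hom/hemi), optional \code{cadd}, \code{gnomad_af},
#'   \code{structural}.
#' @param params \code{\link{triageParams}}.
#' @param rules Gene rules from \code{\link{loadGeneRules}}.
#' @return The input with added columns \code{consequence},
#'   \code{context}, \code{keep} and \code{rule}.
#' @export
triageVariants <- function(variants, params = triageParams(),
                           rules = loadGeneRules()) {
  v <- variants
  if (is.null(v$cadd)) v$cadd <- NA_real_
  if (is.null(v$gnomad_af)) v$gnomad_af <- NA_real_
  if (is.null(v$structural)) v$structural <- FALSE
  v$consequence <- classifyConsequence(v$cdna, v$protein, v$structural)
  v$context <- .zygosityContext(v$family, v$gene, v$zygosity)
  f1 <- frequencyCaddFilter(v$cadd, v$gnomad_af, v$context, params)
  f2 <- applyGeneRules(v$gene, v$genomic, v$consequence, rules)
  v$keep <- f1$keep & f2$keep
  v$rule <- ifelse(!f1$keep, f1$rule,
                   ifelse(!f2$keep, f2$rule, "pass"))
  v
}

#' Assemble inheritance-mode diagnosis candidates per family
#'
#' Per family and gene: a homozygous genotype or two or more heterozygous
#' variants in an AR-capable gene forms a recessive candidate (compound
#' heterozygotes flagged unphased); a single heterozygous variant in an
#' AD-capable gene forms a dominant candidate; any qualifying variant in
#' the X-linked gene (heterozygous female or hemizygous male) forms an XL
#' candidate; a single heterozygous variant in an AR-only gene is a
#' carrier note, not a candidate.
#'
#' @param variants Kept variants (e.g. \code{keep == TRUE} rows of
#'   \code{\link{triageVariants}}), with \code{family}, \code{gene},
#'   \code{genomic}, \code{zygosity}, \code{consequence}, optional
#'   \code{sex} and \code{primary} columns.
#' @param modes Named list, gene symbol to mode set (see
#'   \code{\link{panelModes}}); unknown gene symbols are an error.
#' @return data.frame of candidates: \code{family}, \code{gene},
#'   \code{mode}, \code{genotype}, \code{nVariants}, \code{unphased},
#'   \code{primary}, \code{status} (\code{candidate} or \code{carrier}),
#'   \code{variants} (semicolon-joined genomic keys).
#' @export
assembleDiagnoses <- function(variants, modes) {
  unknown <- setdiff(unique(variants$gene), names(modes))
  if (length(unknown)) {
    stop("input error: unknown gene symbol(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(variants$primary)) variants$primary <- TRUE
  if (is.null(variants$sex)) variants$sex <- NA_character_
  rows <- list()
  for (fam in unique(variants$family)) {
    vf <- variants[variants$family == fam, , drop = FALSE]
    for (g in unique(vf$gene)) {
      vg <- vf[vf$gene == g, , drop = FALSE]
      m <- modes[[g]]
      nHet <- sum(vg$zygosity == "het")
      nHom <- sum(vg$zygosity == "hom")
      nHemi <- sum(vg$zygosity == "hemi")
      mode <- NA_character_; genotype <- NA_character_
      status <- "candidate"; unphased <- FALSE
      if ("XL" %in% m) {
        if (nHemi >= 1L) genotype <- "hemizygous"
        else if (nHet >= 1L) genotype <- "heterozygous"
        if (!is.na(genotype)) mode <- "XL" else next
      } else if (nHom >= 1L && "AR" %in% m) {
        mode <- "AR"; genotype <- "homozygous"
      } else if (nHet >= 2L && "AR" %in% m) {
        mode <- "AR"; genotype <- "compound_het"; unphased <- TRUE
      } else if (nHet >= 1L && "AD" %in% m) {
        mode <- "AD"; genotype <- "heterozygous"
      } else if (nHet == 1L && identical(m, "AR")) {
        mode <- "AR"; genotype <- "heterozygous"; status <- "carrier"
      } else if (nHom >= 1L && "AD" %in% m) {
        mode <- "AD"; genotype <- "homozygous"
      } else {
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, gene = g, mode = mode, genotype = genotype,
        nVariants = nrow(vg), unphased = unphased,
        primary = any(vg$primary), status = status,
        variants = paste(vg$genomic, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), gene = character(0),
               mode = character(0), genotype = character(0),
               nVariants = integer(0), unphased = logical(0),
               primary = logical(0), status = character(0),
               variants = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Report families with candidates in two or more genes
#'
#' @param candidates Output of \code{\link{assembleDiagnoses}}.
#' @return data.frame with one row per digenic family: \code{family},
#'   \code{genes} (comma-joined), \code{primaryGene} (the gene of the
#'   family's primary candidate) and \code{genotypes}.
#' @export
digenicReport <- function(candidates) {
  cand <- candidates[candidates$status == "candidate", , drop = FALSE]
  rows <- list()
  for (fam in unique(cand$family)) {
    cf <- cand[cand$family == fam, , drop = FALSE]
    if (length(unique(cf$gene)) < 2L) next
    prim <- cf$gene[cf$primary]
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, genes = paste(sort(unique(cf$gene)), collapse = ","),
      primaryGene = if (length(prim)) prim[1L] else NA_character_,
      genotypes = paste(paste0(cf$gene, ":", cf$genotype),
                        collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), genes = character(0),
               primaryGene = character(0), genotypes = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Load the packaged screening-cohort fixture
#'
#' A transcription of the reported per-family variant tables of a 181
#' proband amelogenesis imperfecta screening cohort: family id, gene,
#' genomic/cDNA/protein nomenclature, zygosity, CADD score, population
#' frequency and the reported classification (carried as a read-only
#' label). Secondary-gene records of the digenic families are included
#' with \code{primary = FALSE}.
#'
#' @return data.frame ready for \code{\link{triageVariants}} and
#'   \code{\link{assembleDiagnoses}}.
#' @export
loadReportedCohort <- function() {
  tab <- read.delim(.extdata("ai_cohort_variants.tsv"),
                    colClasses = "character")
  tab$family <- as.character(tab$family)
  tab$cadd <- .numOrNA(tab$cadd)
  tab$gnomad_af <- .numOrNA(tab$gnomad_af)
  tab$structural <- tab$structural == "TRUE"
  tab$primary <- tab$primary == "TRUE"
  tab$sex[tab$sex == ""] <- NA_character_
  tab
}

#' Load the packaged FAM83H upstream-exon exclusion example
#'
#' A single recurrent truncating FAM83H variant record lying outside the
#' last-exon interval, with a population frequency above the monoallelic
#' ceiling; it is excluded by two independent cascade rules and is
#' packaged separately from the cohort fixture. Its genomic coordinate
#' is synthetic (approximate placement upstream of the last-exon
#' boundary).
#'
#' @return One-row data.frame in the cohort-fixture layout.
#' @export
fam83hExampleRecord <- function() {
  tab <- read.delim(.extdata("fam83h_exon3_example_synthetic.tsv"),
                    colClasses = "character")
  tab$cadd <- .numOrNA(tab$cadd)
  tab$gnomad_af <- .numOrNA(tab$gnomad_af)
  tab$structural <- FALSE
  tab$primary <- TRUE
  tab
}

#' Summarise a triaged cohort
#'
#' Counts solved families (at least one qualifying candidate), per-mode
#' and per-gene family counts (per family, the primary candidate), the
#' number of distinct variants across primary candidates (deduplicated
#' by genomic key), per-consequence-class tallies over those distinct
#' variants, and the solved percentage (rounded to the nearest integer,
#' half away from zero).
#'
#' @param candidates Output of \code{\link{assembleDiagnoses}}.
#' @param cohortSize Number of probands screened (> 0).
#' @param triaged Optional triaged variant table (from
#'   \code{\link{triageVariants}}) used for the per-class tallies.
#' @return List with \code{solved}, \code{perMode}, \code{perGene},
#'   \code{distinctVariants}, \code{perClass}, \code{percentSolved} and
#'   \code{cohortSize}.
#' @export
summarizeCohort <- function(candidates, cohortSize, triaged = NULL) {
  if (cohortSize <= 0L) {
    stop("input error: cohort size must be positive", call. = FALSE)
  }
  cand <- candidates[candidates$status == "candidate", , drop = FALSE]
  fams <- unique(cand$family)
  # per family, the primary candidate (first candidate as fallback)
  pick <- lapply(fams, function(fam) {
    cf <- cand[cand$family == fam, , drop = FALSE]
    if (any(cf$primary)) cf[which(cf$primary)[1L], ] else cf[1L, ]
  })
  pick <- do.call(rbind, pick)
  perMode <- if (is.null(pick)) integer(0) else
    table(factor(pick$mode, levels = c("XL", "AD", "AR")))
  geneTab <- if (is.null(pick)) integer(0) else
    sort(table(pick$gene), decreasing = TRUE)
  primKeys <- unique(unlist(strsplit(
    cand$variants[cand$primary], ";", fixed = TRUE)))
  perClass <- NULL
  if (!is.null(triaged) && length(primKeys)) {
    t1 <- triaged[!duplicated(triaged$genomic) &
                    triaged$genomic %in% primKeys, , drop = FALSE]
    perClass <- table(factor(t1$consequence,
                             levels = c("missense", "nonsense",
                                        "frameshift", "splice",
                                        "large_deletion", "other")))
  }
  solved <- length(fams)
  list(solved = solved,
       perMode = perMode,
       perGene = geneTab,
       distinctVariants = length(primKeys),
       perClass = perClass,
       percentSolved = as.integer(.roundHalfAway(100 * solved /
                                                   cohortSize)),
       cohortSize = as.integer(cohortSize))
}

#' Replay the full triage cascade over the packaged cohort fixture
#'
#' Convenience wrapper: loads the cohort fixture and the 19-gene panel,
#' runs consequence classification, the CADD/frequency cascade, gene
#' rules and inheritance-mode assembly, and summarises the cohort.
#'
#' @param cohortSize Probands screened; default 181.
#' @param params \code{\link{triageParams}}.
#' @return List with \code{triaged}, \code{candidates}, \code{digenic}
#'   and \code{summary}.
#' @examples
#' res <- replayCohort()
#' res$summary$solved
#' @export
replayCohort <- function(cohortSize = 181L, params = triageParams()) {
  cohort <- loadReportedCohort()
  panel <- loadPanelFixture("ai19")
  triaged <- triageVariants(cohort, params)
  kept <- triaged[triaged$keep, , drop = FALSE]
  candidates <- assembleDiagnoses(kept, panelModes(panel))
  list(triaged = triaged,
       candidates = candidates,
       digenic = digenicReport(candidates),
       summary = summarizeCohort(candidates, cohortSize, triaged))
}

#' Write a cohort summary as JSON
#'
#' @param summary Output of \code{\link{summarizeCohort}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCohortSummary <- function(summary, path) {
  x <- list(solved = summary$solved,
            percent_solved = summary$percentSolved,
            cohort_size = summary$cohortSize,
            distinct_variants = summary$distinctVariants,
            per_mode = as.list(summary$perMode),
            per_gene = as.list(summary$perGene))
  if (!is.null(summary$perClass)) {
    x$per_class <- as.list(summary$perClass)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Annotate variant calls with an external annotation table
#'
#' Left join on the (contig, pos, ref, alt) key; duplicate keys in the
#' annotation table are an input error, calls absent from the table are
#' flagged unannotated with empty annotation fields.
#'
#' @param calls Call data.frame (\code{contig}, \code{pos}, \code{ref},
#'   \code{alt}, ...).
#' @param annotations data.frame with the key columns plus annotation
#'   fields (e.g. \code{gene}, \code{cadd}, \code{gnomad_af},
#'   \code{cdna}, \code{protein}).
#' @return The calls with annotation columns appended and an
#'   \code{annotated} flag.
#' @export
annotateCalls <- function(calls, annotations) {
  key <- function(df) paste(df$contig, df$pos, df$ref, df$alt,
                            sep = "\r")
  ak <- key(annotations)
  if (anyDuplicated(ak)) {
    stop("input error: duplicate keys in annotation table",
         call. = FALSE)
  }
  idx <- match(key(calls), ak)
  extra <- annotations[idx, setdiff(names(annotations),
                                    c("contig", "pos", "ref", "alt")),
                       drop = FALSE]
  rownames(extra) <- NULL
  out <- cbind(calls, extra)
  out$annotated <- !is.na(idx)
  out
}
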