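# Standard genetic code, built once at load.
GENETIC_CODE_1 <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' KRAS assay reference
#'
#' The two amplicons of the assay (hg19, 1-based, both on the minus strand —
#' KRAS is transcribed from the reverse strand): chr12:25,398,271-25,398,309
#' covering codons 4-16 and chr12:25,380,228-25,380,307 covering codons 51
#' onward, together 119 bp. The packaged coding-sequence segment spans codons
#' 1-77 so that every screened codon translates.
#'
#' @return list with `amplicons` (data frame: contig, start, end, anchor —
#'   the genomic coordinate g maps to cDNA position `anchor - g`), `cds`
#'   (character string), `n_codons`.
#' @export
kras_reference <- function() {
  cds_path <- system.file("extdata", "kras_cds_codons1-77.txt",
                          package = "plasmakras", mustWork = TRUE)
  cds <- readLines(cds_path, warn = FALSE)[1]
  list(
    amplicons = data.frame(
      name = c("ex2_codons4_16", "ex3_codons51_69"),
      contig = "chr12",
      start = c(25398271L, 25380228L),
      end = c(25398309L, 25380307L),
      anchor = c(25398319L, 25380458L),
      stringsAsFactors = FALSE),
    cds = cds,
    n_codons = nchar(cds) %/% 3L
  )
}

#' Map a genomic substitution to cDNA coordinates
#'
#' KRAS is on the minus strand, so the genomic ref/alt bases are
#' reverse-complemented and the cDNA position counts from the translation
#' start. Within each amplicon the mapping is `cdna = anchor - pos`.
#'
#' @param pos genomic position (1-based, hg19 chr12).
#' @param ref,alt genomic (plus-strand) bases.
#' @param reference a [kras_reference()] list.
#' @return list with `cdna_pos`, `cdna_ref`, `cdna_alt`.
#' @export
genomic_to_cdna <- function(pos, ref, alt, reference = kras_reference()) {
  amp <- reference$amplicons
  hit <- which(pos >= amp$start & pos <= amp$end)
  if (length(hit) != 1) {
    stop("off-target: chr12:", pos, " lies outside the assay amplicons")
  }
  cdna_pos <- amp$anchor[hit] - pos
  cdna_ref <- COMPLEMENT[[toupper(ref)]]
  expected <- substr(reference$cds, cdna_pos, cdna_pos)
  if (cdna_ref != expected) {
    stop(sprintf("reference mismatch at chr12:%d: genomic %s implies cDNA %s but CDS has %s",
                 pos, ref, cdna_ref, expected))
  }
  list(cdna_pos = cdna_pos, cdna_ref = cdna_ref,
       cdna_alt = COMPLEMENT[[toupper(alt)]])
}

#' @rdname genomic_to_cdna
#' @param cdna_pos cDNA position within an amplicon.
#' @export
cdna_to_genomic <- function(cdna_pos, reference = kras_reference()) {
  amp <- reference$amplicons
  g <- amp$anchor - cdna_pos
  hit <- which(g >= amp$start & g <= amp$end)
  if (length(hit) != 1) stop("cDNA position ", cdna_pos, " lies outside the assay amplicons")
  g[hit]
}

#' Annotate a cDNA substitution
#'
#' Composes HGVS c. and p. strings (one-letter amino-acid style, e.g.
#' `p.G12V`), determines the codon (`ceiling(cdna_pos/3)`) and whether the
#' change is missense or silent by translating the mutant codon against the
#' packaged reference CDS.
#'
#' @param cdna_pos cDNA position (1-based from the translation start).
#' @param ref,alt cDNA-strand bases.
#' @param reference a [kras_reference()].
#' @return list of class `kras_annotation`: `cdna`, `protein`, `codon`,
#'   `consequence` ("missense" or "silent"), `aa_ref`, `aa_alt`.
#' @export
annotate_substitution <- function(cdna_pos, ref, alt, reference = kras_reference()) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (cdna_pos < 1 || cdna_pos > nchar(reference$cds)) {
    stop("cDNA position ", cdna_pos, " outside the packaged CDS segment")
  }
  have <- substr(reference$cds, cdna_pos, cdna_pos)
  if (have != ref) {
    stop(sprintf("reference error: CDS has %s at c.%d, not %s", have, cdna_pos, ref))
  }
  codon_idx <- as.integer(ceiling(cdna_pos / 3))
  codon_start <- 3L * (codon_idx - 1L) + 1L
  ref_codon <- substr(reference$cds, codon_start, codon_start + 2L)
  offset <- cdna_pos - codon_start + 1L
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt
  aa_ref <- GENETIC_CODE_1[[ref_codon]]
  aa_alt <- GENETIC_CODE_1[[alt_codon]]
  structure(list(
    cdna = sprintf("c.%d%s>%s", cdna_pos, ref, alt),
    protein = sprintf("p.%s%d%s", aa_ref, codon_idx, aa_alt),
    codon = codon_idx,
    consequence = if (aa_ref == aa_alt) "silent" else "missense",
    aa_ref = aa_ref, aa_alt = aa_alt
  ), class = "kras_annotation")
}

#' @export
print.kras_annotation <- function(x, ...) {
  cat(sprintf("KRAS %s; %s (%s)\n", x$cdna, x$protein, x$consequence))
  invisible(x)
}

#' Default SNP exclusion list
#'
#' One cDNA change per line; ships with c.24A>G (rs147406419, p.V8V), a rare
#' germline variant that must never enter the somatic tallies.
#'
#' @param path optional alternative file.
#' @export
snp_exclusion_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "snp_exclude.txt",
                        package = "plasmakras", mustWork = TRUE)
  }
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Classify an annotated substitution into reporting categories
#'
#' Categories: `snp_excluded` (on the exclusion list — contributes nothing
#' downstream), `hotspot_pdac` (missense at codon 12, 13 or 61 — the codons
#' recurrently mutated in pancreatic ductal adenocarcinoma), `silent`
#' (synonymous), and `other_cosmic_codon` (any other missense within the
#' amplicons; an optional allow-list can restrict this further, since
#' database membership is version-dependent).
#'
#' @param annotation a `kras_annotation`.
#' @param snp_list character vector of excluded c. changes.
#' @param cosmic_allow optional character vector of allowed non-hotspot
#'   protein changes; `NULL` (default) accepts all.
#' @export
classify_annotation <- function(annotation, snp_list = snp_exclusion_list(),
                                cosmic_allow = NULL) {
  stopifnot(inherits(annotation, "kras_annotation"))
  if (annotation$cdna %in% snp_list) return("snp_excluded")
  if (annotation$consequence == "silent") return("silent")
  if (annotation$codon %in% c(12L, 13L, 61L)) return("hotspot_pdac")
  if (!is.null(cosmic_allow) && !(annotation$protein %in% cosmic_allow)) {
    return("other_non_cosmic")
  }
  "other_cosmic_codon"
}

#' Annotate a table of variant calls
#'
#' Convenience wrapper: maps each genomic call through [genomic_to_cdna()],
#' [annotate_substitution()] and [classify_annotation()], appending `cdna`,
#' `protein`, `codon`, `consequence` and `category` columns.
#'
#' @param calls data frame with `pos`, `ref`, `alt` (genomic, plus strand).
#' @param snp_list,cosmic_allow passed to [classify_annotation()].
#' @param reference a [kras_reference()].
#' @export
annotate_calls <- function(calls, snp_list = snp_exclusion_list(),
                           cosmic_allow = NULL, reference = kras_reference()) {
  if (nrow(calls) == 0) {
    calls$cdna <- character(0); calls$protein <- character(0)
    calls$codon <- integer(0); calls$consequence <- character(0)
    calls$category <- character(0)
    return(calls)
  }
  ann <- lapply(seq_len(nrow(calls)), function(i) {
    m <- genomic_to_cdna(calls$pos[i], calls$ref[i], calls$alt[i], reference)
    a <- annotate_substitution(m$cdna_pos, m$cdna_ref, m$cdna_alt, reference)
    c(a[c("cdna", "protein", "consequence")], codon = a$codon,
      category = classify_annotation(a, snp_list, cosmic_allow))
  })
  calls$cdna <- vapply(ann, `[[`, character(1), "cdna")
  calls$protein <- vapply(ann, `[[`, character(1), "protein")
  calls$codon <- vapply(ann, `[[`, integer(1), "codon")
  calls$consequence <- vapply(ann, `[[`, character(1), "consequence")
  calls$category <- vapply(ann, `[[`, character(1), "category")
  calls
}

#' Parse an HGVS c. substitution string
#'
#' `"c.35G>T"` -> list(cdna_pos = 35, ref = "G", alt = "T"). Used by the
#' fixture loaders and the cohort simulator.
#'
#' @param x character vector of c. strings.
#' @export
parse_cdna <- function(x) {
  m <- regmatches(x, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("malformed c. string: ", x[bad][1])
  data.frame(cdna_pos = as.integer(vapply(m, `[`, character(1), 2)),
             ref = vapply(m, `[`, character(1), 3),
             alt = vapply(m, `[`, character(1), 4),
             stringsAsFactors = FALSE)
}
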