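#' Strand-resolved site-by-sample count matrix
#'
#' The caller's sole input: one row per (site, alternate base, sample) holding
#' strand-resolved depth and variant-read counts from amplicon deep
#' sequencing. `DP_p`/`DP_m` are forward/reverse read depths, `AO_p`/`AO_m`
#' the forward/reverse reads matching the candidate variant. Total depth
#' `DP = DP_p + DP_m` and variant reads `AO = AO_p + AO_m` are always derived,
#' never stored.
#'
#' @param contig,pos,ref,alt site identity; `pos` is 1-based on hg19 contig
#'   labels (`"ch12"` is normalised to `"chr12"`).
#' @param sample sample identifier.
#' @param DP_p,DP_m,AO_p,AO_m non-negative integer counts with
#'   `AO_p <= DP_p`, `AO_m <= DP_m`.
#' @return A `data.frame` of class `site_count_matrix`.
#' @export
site_count_matrix <- function(contig, pos, ref, alt, sample,
                              DP_p, DP_m, AO_p, AO_m) {
  x <- data.frame(
    contig = normalize_contig(as.character(contig)),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    sample = as.character(sample),
    DP_p = as.integer(DP_p), DP_m = as.integer(DP_m),
    AO_p = as.integer(AO_p), AO_m = as.integer(AO_m),
    stringsAsFactors = FALSE
  )
  validate_site_count_matrix(x)
}

normalize_contig <- function(x) sub("^ch(?=[0-9XYM])", "chr", x, perl = TRUE)

#' @rdname site_count_matrix
#' @param x data frame with the `site_count_matrix` columns.
#' @export
validate_site_count_matrix <- function(x) {
  need <- c("contig", "pos", "ref", "alt", "sample",
            "DP_p", "DP_m", "AO_p", "AO_m")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("count matrix is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  bad <- which(!(x$ref %in% bases) | !(x$alt %in% bases))
  if (length(bad) > 0) {
    stop("unknown ref/alt base in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(x$ref == x$alt)) {
    stop("ref and alt must differ (row ", which(x$ref == x$alt)[1], ")")
  }
  cnt <- c("DP_p", "DP_m", "AO_p", "AO_m")
  for (cc in cnt) {
    if (any(is.na(x[[cc]])) || any(x[[cc]] < 0)) {
      stop("negative or missing count in column ", cc)
    }
  }
  bad <- which(x$AO_p > x$DP_p | x$AO_m > x$DP_m)
  if (length(bad) > 0) {
    i <- bad[1]
    stop(sprintf("AO exceeds DP for site %s:%d %s>%s sample %s",
                 x$contig[i], x$pos[i], x$ref[i], x$alt[i], x$sample[i]))
  }
  dup <- duplicated(x[, c("contig", "pos", "ref", "alt", "sample")])
  if (any(dup)) stop("duplicated (site, alt, sample) row: ", which(dup)[1])
  class(x) <- c("site_count_matrix", "data.frame")
  x
}

#' @rdname site_count_matrix
#' @export
scm_dp <- function(x) x$DP_p + x$DP_m

#' @rdname site_count_matrix
#' @export
scm_ao <- function(x) x$AO_p + x$AO_m

#' @export
print.site_count_matrix <- function(x, ...) {
  nsite <- nrow(unique(x[, c("contig", "pos", "ref", "alt")]))
  cat(sprintf("site_count_matrix: %d site/alt pairs x %d samples (%d rows)\n",
              nsite, length(unique(x$sample)), nrow(x)))
  NextMethod()
}

#' Read a strand-resolved count table
#'
#' Canonical dialect is long format (tab-separated, header
#' `contig pos ref alt sample DP_p DP_m AO_p AO_m`). A wide dialect with one
#' column block of `<sample>.DP_p` ... `<sample>.AO_m` per sample is supported
#' read-only.
#'
#' @param path file path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @return A validated [site_count_matrix].
#' @export
read_count_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  x <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed count table '", path, "': ",
                             conditionMessage(e))
  )
  if (dialect == "long") {
    return(validate_site_count_matrix(x))
  }
  fixed <- c("contig", "pos", "ref", "alt")
  if (!all(fixed %in% names(x))) stop("wide table must carry columns contig/pos/ref/alt")
  cellcols <- setdiff(names(x), fixed)
  parts <- strsplit(cellcols, ".", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) == 2 &&
                 p[2] %in% c("DP_p", "DP_m", "AO_p", "AO_m"), logical(1))
  if (!all(ok)) stop("wide table columns must be named <sample>.<DP_p|DP_m|AO_p|AO_m>")
  samples <- unique(vapply(parts, `[`, character(1), 1))
  long <- do.call(rbind, lapply(samples, function(s) {
    data.frame(x[fixed], sample = s,
               DP_p = x[[paste0(s, ".DP_p")]], DP_m = x[[paste0(s, ".DP_m")]],
               AO_p = x[[paste0(s, ".AO_p")]], AO_m = x[[paste0(s, ".AO_m")]],
               stringsAsFactors = FALSE)
  }))
  validate_site_count_matrix(long)
}

#' @rdname read_count_table
#' @param x a [site_count_matrix].
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "site_count_matrix"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a text pileup stream into a count matrix
#'
#' Consumes the samtools mpileup text dialect (one line per position:
#' contig, 1-based pos, ref base, depth, read-bases string, base qualities)
#' for a single sample and tallies per-strand match/mismatch counts at the
#' assay target sites. Case encodes strand in the read-bases string
#' (`.`/uppercase = forward, `,`/lowercase = reverse). Bases below
#' `min_base_quality` are excluded from both DP and AO. Indel blocks and
#' read start/end marks are skipped (the assay targets substitutions only);
#' skipped indels are reported via a message. The mapping-quality filter
#' (MQ >= 20 in the assay) is an upstream, BAM-level contract: pileup text
#' carries no mapping quality, so this parser assumes it has been applied.
#'
#' @param lines character vector of pileup lines (or a connection path given
#'   to [readLines()] by the caller).
#' @param targets data frame with columns `contig`, `pos`, `ref`, `alt`
#'   defining the (site, alt) pairs to tally.
#' @param sample sample identifier for the resulting matrix.
#' @param min_base_quality Phred floor; default 0 (the assay filters on
#'   mapping quality only).
#' @return A [site_count_matrix] over `targets` (zero counts where the
#'   pileup has no data).
#' @export
parse_pileup <- function(lines, targets, sample = "S1", min_base_quality = 0) {
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(targets)))
  targets$contig <- normalize_contig(as.character(targets$contig))
  out <- data.frame(targets[, c("contig", "pos", "ref", "alt")],
                    sample = sample, DP_p = 0L, DP_m = 0L, AO_p = 0L, AO_m = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) stop("malformed pileup line ", i, ": fewer than 6 fields")
    contig <- normalize_contig(f[1])
    pos <- as.integer(f[2])
    hit <- which(out$contig == contig & out$pos == pos)
    if (length(hit) == 0) {
      message("pileup line ", i, " at ", contig, ":", pos, " outside targets; skipped")
      next
    }
    parsed <- parse_pileup_bases(f[5], f[6], line_no = i)
    keep <- parsed$qual >= min_base_quality
    b <- parsed$base[keep]
    fwd <- parsed$forward[keep]
    for (h in hit) {
      out$DP_p[h] <- sum(fwd)
      out$DP_m[h] <- sum(!fwd)
      is_alt <- toupper(b) == out$alt[h]
      out$AO_p[h] <- sum(is_alt & fwd)
      out$AO_m[h] <- sum(is_alt & !fwd)
    }
  }
  validate_site_count_matrix(out)
}

# Tokenize one read-bases string with its quality string. Returns, per
# counted base, the called base ('.'/',' resolved to 'R' for reference),
# strand, and numeric quality (Phred+33).
parse_pileup_bases <- function(bases, quals, line_no = NA) {
  chars <- strsplit(bases, "")[[1]]
  qv <- as.integer(charToRaw(quals)) - 33L
  base <- character(0); forward <- logical(0); qual <- integer(0)
  qi <- 0L
  i <- 1L
  n_indel <- 0L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "^") {       # read start: next char is mapping quality
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {  # indel block: [+-](\d+)bases
      j <- i + 1L
      num <- ""
      while (j <= length(chars) && grepl("[0-9]", chars[j])) {
        num <- paste0(num, chars[j]); j <- j + 1L
      }
      i <- j + as.integer(num)
      n_indel <- n_indel + 1L
    } else if (ch %in% c("*", "#")) {  # deletion placeholder consumes a quality
      qi <- qi + 1L
      i <- i + 1L
    } else {
      qi <- qi + 1L
      if (qi > length(qv)) {
        stop("ragged pileup bases/qualities at line ", line_no)
      }
      if (ch %in% c(".", ",")) {
        base <- c(base, "R")
        forward <- c(forward, ch == ".")
      } else if (toupper(ch) %in% c("A", "C", "G", "T", "N")) {
        base <- c(base, toupper(ch))
        forward <- c(forward, ch %in% c("A", "C", "G", "T", "N"))
      } else {
        stop("unexpected pileup symbol '", ch, "' at line ", line_no)
      }
      qual <- c(qual, qv[qi])
      i <- i + 1L
    }
  }
  if (qi != length(qv)) stop("ragged pileup bases/qualities at line ", line_no)
  if (n_indel > 0) message("skipped ", n_indel, " indel block(s) at line ", line_no)
  list(base = base, forward = forward, qual = qual)
}

#' Write variant calls as VCF 4.2
#'
#' One record per (site, alt); QVAL goes in the QUAL column and AF, AO, DP and
#' RVSB travel as per-sample FORMAT fields. All fields are declared in the
#' header.
#'
#' @param calls a `variant_calls` data frame from [call_variants()] (columns
#'   `sample`, `contig`, `pos`, `ref`, `alt`, `DP`, `AO`, `AF`, `QVAL`,
#'   `RVSB`, `filter`).
#' @param samples full sample list for the GT columns; defaults to the
#'   samples present in `calls`.
#' @param path output file path.
#' @export
write_vcf <- function(calls, path, samples = NULL) {
  if (is.null(samples)) samples <- unique(calls$sample)
  if (nrow(calls) > 0) {
    dup <- duplicated(calls[, c("contig", "pos", "ref", "alt", "sample")])
    if (any(dup)) stop("duplicate call for one (site, alt, sample): row ", which(dup)[1])
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=plasmakras",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of samples called\">",
    "##FILTER=<ID=strand_bias,Description=\"RVSB above the configured maximum\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AO,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allelic fraction AO/DP\">",
    "##FORMAT=<ID=RVSB,Number=1,Type=Float,Description=\"Relative variant strand bias\">",
    "##FORMAT=<ID=QVAL,Number=1,Type=Float,Description=\"Phred-scaled q-value\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rec <- character(0)
  if (nrow(calls) > 0) {
    key <- paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
    for (k in unique(key)) {
      cc <- calls[key == k, , drop = FALSE]
      filt <- if (any(cc$filter != "PASS")) {
        paste(setdiff(unique(cc$filter), "PASS"), collapse = ";")
      } else "PASS"
      gt <- vapply(samples, function(s) {
        j <- which(cc$sample == s)
        if (length(j) == 0) return("./.")
        sprintf("%d:%d:%.6g:%.4g:%.4g", cc$DP[j[1]], cc$AO[j[1]],
                cc$AF[j[1]], cc$RVSB[j[1]], cc$QVAL[j[1]])
      }, character(1))
      rec <- c(rec, paste(c(cc$contig[1], cc$pos[1], ".", cc$ref[1], cc$alt[1],
                            sprintf("%.4g", max(cc$QVAL)), filt,
                            paste0("NS=", nrow(cc)), "DP:AO:AF:RVSB:QVAL", gt),
                          collapse = "\t"))
    }
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read back a VCF written by [write_vcf()]
#'
#' Minimal reader for round-trip checks; returns one row per (site, alt,
#' sample) with the FORMAT fields decoded.
#'
#' @param path VCF path.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  rows <- list()
  for (ln in body[-1]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    for (i in seq_along(samples)) {
      g <- f[9 + i]
      if (g == "./.") next
      v <- as.numeric(strsplit(g, ":", fixed = TRUE)[[1]])
      rows[[length(rows) + 1]] <- data.frame(
        contig = f[1], pos = as.integer(f[2]), ref = f[4], alt = f[5],
        sample = samples[i], DP = v[1], AO = v[2], AF = v[3],
        RVSB = v[4], QVAL = v[5], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), sample = character(0), DP = numeric(0),
                      AO = numeric(0), AF = numeric(0), RVSB = numeric(0),
                      QVAL = numeric(0)))
  }
  do.call(rbind, rows)
}
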