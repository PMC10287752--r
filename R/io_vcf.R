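#' Construct a variant-call table
#'
#' The unit record of the audit pipeline: one row per (chrom, pos, ref, alt)
#' call from one caller. Depths and allele frequency may be missing (`NA`),
#' which downstream code treats as "unmeasured" — a distinct state from 0.
#'
#' @param caller_id,chrom,pos,ref,alt,ref_depth,alt_depth,allele_frequency
#'   vectors, recycled to a common length.
#' @return data.frame of class `variant_calls`.
#' @export
variant_calls <- function(caller_id, chrom, pos, ref, alt,
                          ref_depth = NA_integer_, alt_depth = NA_integer_,
                          allele_frequency = NA_real_) {
  n <- max(length(caller_id), length(chrom), length(pos), length(ref),
           length(alt))
  df <- data.frame(
    caller_id = rep_len(as.character(caller_id), n),
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    ref_depth = rep_len(as.integer(ref_depth), n),
    alt_depth = rep_len(as.integer(alt_depth), n),
    allele_frequency = rep_len(as.numeric(allele_frequency), n),
    stringsAsFactors = FALSE
  )
  validate_variant_calls(df)
}

#' Validate a variant-call table against its invariants
#'
#' Checks positions are >= 1, REF/ALT are non-empty ACGT strings with
#' ref != alt, depths are non-negative, and that any recorded allele
#' frequency is consistent (within 1e-6) with recorded depths.
#'
#' @param df data.frame with the `variant_calls` columns.
#' @return the validated data.frame (invisibly classed).
#' @export
validate_variant_calls <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("caller_id", "chrom", "pos", "ref", "alt",
              "ref_depth", "alt_depth", "allele_frequency")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    if (any(is.na(df$pos) | df$pos < 1L))
      stop("pos must be >= 1", call. = FALSE)
    bad <- !nzchar(df$ref) | !nzchar(df$alt) |
      grepl("[^ACGT]", df$ref) | grepl("[^ACGT]", df$alt)
    if (any(bad))
      stop("non-ACGT or empty allele in record(s) ",
           paste(utils::head(which(bad), 5L), collapse = ","), call. = FALSE)
    if (any(df$ref == df$alt))
      stop("ref must differ from alt", call. = FALSE)
    if (any(df$ref_depth < 0L | df$alt_depth < 0L, na.rm = TRUE))
      stop("depths must be non-negative", call. = FALSE)
    both <- !is.na(df$ref_depth) & !is.na(df$alt_depth) &
      !is.na(df$allele_frequency)
    tot <- df$ref_depth + df$alt_depth
    chk <- both & tot > 0L
    if (any(chk)) {
      dev <- abs(df$allele_frequency[chk] -
                   df$alt_depth[chk] / tot[chk])
      if (any(dev > 1e-6))
        stop("allele_frequency inconsistent with depths", call. = FALSE)
    }
  }
  class(df) <- unique(c("variant_calls", class(df)))
  df
}

.empty_variant_calls <- function() {
  variant_calls(character(0), character(0), integer(0),
                character(0), character(0))
}

.is_symbolic_allele <- function(alt) {
  grepl("[<>\\[\\]*]", alt) | alt == "." | grepl("^<", alt)
}

#' Read a VCF file into a variant-call table
#'
#' Parses the VCF v4.x subset the audit consumes: CHROM, POS, REF, ALT and,
#' when present, per-sample AD (and AF) from the first sample column.
#' Multi-allelic rows are split into one record per ALT allele; symbolic or
#' breakend alleles are skipped with a warning. When depths are present and
#' AF is not, the frequency is computed as alt/(ref+alt); when neither is
#' present the frequency is unmeasured (`NA`), never 0.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param caller_id short caller label stamped on every record.
#' @return `variant_calls` data.frame, one row per ALT allele, file order
#'   preserved.
#' @export
read_vcf <- function(path, caller_id) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr_lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(hdr_lines, "#CHROM")))
    stop("not a VCF: missing #CHROM header line in ", path, call. = FALSE)
  body <- hdr_lines[!startsWith(hdr_lines, "#")]
  body <- body[nzchar(body)]
  if (!length(body)) return(.empty_variant_calls())

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  has_gt <- ncol(v@gt) >= 2L
  ad_raw <- rep(NA_character_, n)
  af_raw <- rep(NA_character_, n)
  if (has_gt) {
    fmt <- v@gt[, 1L]
    smp <- v@gt[, 2L]
    fmt_fields <- strsplit(fmt, ":", fixed = TRUE)
    smp_fields <- strsplit(smp, ":", fixed = TRUE)
    pick <- function(i, key) {
      k <- match(key, fmt_fields[[i]])
      if (is.na(k) || k > length(smp_fields[[i]])) NA_character_
      else smp_fields[[i]][k]
    }
    ad_raw <- vapply(seq_len(n), pick, character(1), key = "AD")
    af_raw <- vapply(seq_len(n), pick, character(1), key = "AF")
  }
  # INFO AF fallback when no sample-level AF
  info_af <- sub("^.*(?:^|;)AF=([^;]+).*$", "\\1", fix[, "INFO"])
  info_af[!grepl("(^|;)AF=", fix[, "INFO"])] <- NA_character_
  af_raw <- ifelse(is.na(af_raw), info_af, af_raw)

  out <- vector("list", n)
  n_symbolic <- 0L
  for (i in seq_len(n)) {
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    ad <- if (!is.na(ad_raw[i]) && ad_raw[i] != ".")
      suppressWarnings(as.integer(strsplit(ad_raw[i], ",")[[1]]))
    else NULL
    afs <- if (!is.na(af_raw[i]) && af_raw[i] != ".")
      suppressWarnings(as.numeric(strsplit(af_raw[i], ",")[[1]]))
    else NULL
    rows <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (.is_symbolic_allele(alt)) {
        n_symbolic <- n_symbolic + 1L
        next
      }
      if (grepl("[^ACGT]", alt) || grepl("[^ACGT]", ref))
        stop("non-ACGT allele at ", fix[i, "CHROM"], ":", fix[i, "POS"],
             " (", ref, ">", alt, ")", call. = FALSE)
      rd <- if (!is.null(ad) && length(ad) >= j + 1L) ad[1L] else NA_integer_
      adp <- if (!is.null(ad) && length(ad) >= j + 1L) ad[j + 1L] else NA_integer_
      af <- if (!is.null(afs) && length(afs) >= j) afs[j] else NA_real_
      if (is.na(af) && !is.na(rd) && !is.na(adp) && (rd + adp) > 0L)
        af <- adp / (rd + adp)
      rows[[j]] <- data.frame(
        caller_id = caller_id, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref = ref, alt = alt,
        ref_depth = rd, alt_depth = adp, allele_frequency = af,
        stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  if (n_symbolic > 0L)
    warning(n_symbolic, " symbolic/breakend allele(s) skipped in ", path,
            call. = FALSE)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_variant_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_variant_calls(res)
}

#' Write a variant-call table as a VCF file
#'
#' Emits an uncompressed VCF v4.2 with a single sample column carrying
#' AD and AF. Records must be sorted by (chrom, pos) unless `sort = TRUE`.
#' `read_vcf()` on the result reproduces the input field-for-field on the
#' supported subset.
#'
#' @param records `variant_calls` data.frame.
#' @param path output path.
#' @param sort sort records by (chrom, pos) before writing.
#' @param sample_name sample column label.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sort = FALSE, sample_name = "SAMPLE") {
  records <- validate_variant_calls(as.data.frame(records))
  if (nrow(records)) {
    ord <- order(records$chrom, records$pos)
    if (!identical(ord, seq_len(nrow(records)))) {
      if (!sort)
        stop("records not sorted by (chrom, pos); pass sort = TRUE",
             call. = FALSE)
      records <- records[ord, , drop = FALSE]
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=editaudit",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  if (nrow(records)) {
    ad <- ifelse(is.na(records$ref_depth) | is.na(records$alt_depth), ".",
                 paste0(records$ref_depth, ",", records$alt_depth))
    af <- ifelse(is.na(records$allele_frequency), ".",
                 formatC(records$allele_frequency, digits = 17,
                         format = "g"))
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  ".", "PASS", ".", "GT:AD:AF",
                  paste("./.", ad, af, sep = ":"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
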