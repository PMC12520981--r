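#' Read a barcoded 4DN-style pairs file
#'
#' Parses the 4DN pairs text dialect (optionally gzip-compressed): header
#' lines start with `#`, a `#columns:` line declares the fields, and records
#' are tab-separated. The dialect used here carries an extra cell-barcode
#' column and, optionally, a read-ID column grouping the contacts of one
#' sequencing read (multi-way walks).
#'
#' Records are normalised to the upper triangle: anchors are swapped so that
#' (chrom1, pos1) <= (chrom2, pos2) under the genome's chromosome order.
#' Records on chromosomes absent from `genome` are either skipped and counted
#' (`strict = FALSE`, default) or raise an error.
#'
#' @param path pairs file (plain text or `.gz`).
#' @param genome an `sc_genome`; restricts chromosomes.
#' @param barcode_col name of the cell-barcode column (default `"barcode"`).
#' @param readid_col name of the optional read-ID column (default `"readID"`).
#' @param strict if `TRUE`, unknown chromosomes are an error.
#' @return A tibble of class `sc_pairs` with columns `barcode`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2` and, when present, `read_id`. Attributes:
#'   `genome`, `n_skipped` (records on unknown chromosomes), `n_malformed`.
#' @export
read_pairs <- function(path, genome, barcode_col = "barcode",
                       readid_col = "readID", strict = FALSE) {
  stopifnot(file.exists(path), inherits(genome, "sc_genome"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  colline <- hdr[startsWith(hdr, "#columns:")]
  if (length(colline) == 0) stop("pairs file lacks a '#columns:' declaration")
  cols <- strsplit(sub("^#columns:\\s*", "", colline[1]), "\\s+")[[1]]
  needed <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(needed %in% cols)) {
    stop("pairs columns must include ", paste(needed, collapse = ", "))
  }
  if (!barcode_col %in% cols) {
    stop("pairs file has no barcode column '", barcode_col,
         "'; declared columns: ", paste(cols, collapse = ", "))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= length(cols)
  n_malformed <- sum(!ok)
  fields <- fields[ok]
  m <- matrix(unlist(lapply(fields, `[`, seq_along(cols))),
              ncol = length(cols), byrow = TRUE)
  colnames(m) <- cols
  df <- tibble::tibble(
    barcode = m[, barcode_col],
    chrom1 = m[, "chrom1"],
    pos1 = as.numeric(m[, "pos1"]),
    chrom2 = m[, "chrom2"],
    pos2 = as.numeric(m[, "pos2"])
  )
  if (readid_col %in% cols) df$read_id <- m[, readid_col]
  known <- df$chrom1 %in% genome$chrom_names & df$chrom2 %in% genome$chrom_names
  if (strict && !all(known)) {
    stop("records on chromosomes absent from genome: ",
         paste(unique(c(df$chrom1[!known], df$chrom2[!known])), collapse = ", "))
  }
  n_skipped <- sum(!known)
  df <- df[known, , drop = FALSE]
  df <- normalize_pairs(df, genome)
  attr(df, "genome") <- genome
  attr(df, "n_skipped") <- n_skipped
  attr(df, "n_malformed") <- n_malformed
  class(df) <- c("sc_pairs", class(df))
  df
}

#' Upper-triangular normalisation of pair records
#'
#' Swaps anchors so (chrom1, pos1) <= (chrom2, pos2) under genome order.
#' @param pairs a pairs tibble.
#' @param genome an `sc_genome` giving the chromosome order.
#' @return the tibble with anchors ordered.
#' @export
normalize_pairs <- function(pairs, genome) {
  c1 <- match(pairs$chrom1, genome$chrom_names)
  c2 <- match(pairs$chrom2, genome$chrom_names)
  swap <- c1 > c2 | (c1 == c2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp_c <- pairs$chrom1[swap]; tmp_p <- pairs$pos1[swap]
    pairs$chrom1[swap] <- pairs$chrom2[swap]
    pairs$pos1[swap] <- pairs$pos2[swap]
    pairs$chrom2[swap] <- tmp_c
    pairs$pos2[swap] <- tmp_p
  }
  pairs
}

#' Write a barcoded pairs file
#'
#' Emits the 4DN text dialect with chromsizes header lines and a `#columns:`
#' declaration including the barcode (and read-ID, if present) column.
#'
#' @param pairs a pairs tibble (as from [read_pairs()] or [simulate_cells()]).
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param genome an `sc_genome`; defaults to the table's `genome` attribute.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, genome = attr(pairs, "genome")) {
  stopifnot(inherits(genome, "sc_genome"))
  has_rid <- "read_id" %in% names(pairs)
  cols <- c("chrom1", "pos1", "chrom2", "pos2", "barcode",
            if (has_rid) "readID")
  hdr <- c(
    "## pairs format v1.0",
    sprintf("#chromsize: %s %s", genome$chrom_names,
            format(genome$chrom_lengths, scientific = FALSE, trim = TRUE)),
    paste("#columns:", paste(cols, collapse = " "))
  )
  body <- paste(
    pairs$chrom1, format(pairs$pos1, scientific = FALSE, trim = TRUE),
    pairs$chrom2, format(pairs$pos2, scientific = FALSE, trim = TRUE),
    pairs$barcode,
    sep = "\t"
  )
  if (has_rid) body <- paste(body, pairs$read_id, sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Classify contacts as cis-short, cis-long or trans
#'
#' A contact is trans when its anchors sit on different chromosomes, cis-long
#' when on the same chromosome with a genomic distance strictly greater than
#' `cis_long_bp` (1 kb by default), and cis-short otherwise.
#'
#' @param pairs a pairs tibble.
#' @param cis_long_bp distance threshold separating cis-short from cis-long.
#' @return the tibble with an added factor column `class` with levels
#'   `cis_short`, `cis_long`, `trans`.
#' @export
classify_contacts <- function(pairs, cis_long_bp = 1000) {
  cls <- ifelse(
    pairs$chrom1 != pairs$chrom2, "trans",
    ifelse(abs(pairs$pos2 - pairs$pos1) > cis_long_bp, "cis_long", "cis_short")
  )
  dplyr::mutate(pairs,
                class = factor(cls, levels = c("cis_short", "cis_long", "trans")))
}

#' Per-cell contact quality control
#'
#' Counts cis-short (<= 1 kb), cis-long (> 1 kb) and trans contacts per
#' barcode and flags cells whose total is strictly greater than `min_pairs`
#' (the threshold is strict, matching a "> 1,000 read pairs" selection rule;
#' it is configurable because sensible cutoffs vary by library).
#'
#' @param pairs a pairs tibble.
#' @param min_pairs minimum total contact count (exclusive).
#' @param cis_long_bp distance threshold passed to [classify_contacts()].
#' @return a tibble with one row per barcode: `barcode`, `total_pairs`,
#'   `cis_short`, `cis_long`, `trans`, `pass_flag`.
#' @export
qc_cells <- function(pairs, min_pairs = 1000, cis_long_bp = 1000) {
  if (nrow(pairs) == 0) {
    return(tibble::tibble(
      barcode = character(), total_pairs = integer(), cis_short = integer(),
      cis_long = integer(), trans = integer(), pass_flag = logical()
    ))
  }
  classify_contacts(pairs, cis_long_bp) |>
    dplyr::count(.data$barcode, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L,
                       names_expand = TRUE) |>
    dplyr::mutate(
      total_pairs = .data$cis_short + .data$cis_long + .data$trans,
      pass_flag = .data$total_pairs > min_pairs
    ) |>
    dplyr::select("barcode", "total_pairs", "cis_short", "cis_long", "trans",
                  "pass_flag")
}

#' Read a BED file of intervals
#' @param path BED3+ text file (0-based half-open).
#' @return tibble with `chrom`, `start` (0-based), `end`, and `name` if present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- tibble::tibble(chrom = as.character(df[[1]]),
                        start = as.numeric(df[[2]]),
                        end = as.numeric(df[[3]]))
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}
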