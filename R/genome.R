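#' Define a genome with a binning scheme
#'
#' A `sc_genome` holds an ordered set of chromosomes with their lengths and a
#' working bin resolution. All bin indices in the package are *global*: bins
#' are numbered 1..B by concatenating per-chromosome bins in chromosome order,
#' with `ceiling(length / resolution)` bins per chromosome. Chromosomes listed
#' in `excluded_chroms` (the Y chromosome by default) are kept in the binning
#' but dropped from trans-contact statistics such as the hub index.
#'
#' @param chrom_names character vector of chromosome identifiers, in order.
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param resolution bin width in bp (default 1 Mb).
#' @param excluded_chroms chromosomes excluded from trans statistics.
#' @return An object of class `sc_genome`.
#' @examples
#' g <- sc_genome(c("chr1", "chr2"), c(5e6, 3e6), resolution = 1e6)
#' n_bins(g) # 8
#' @export
sc_genome <- function(chrom_names, chrom_lengths, resolution = 1e6,
                      excluded_chroms = "chrY") {
  stopifnot(length(chrom_names) == length(chrom_lengths))
  if (anyDuplicated(chrom_names)) stop("duplicated chromosome names")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (resolution <= 0) stop("resolution must be > 0")
  nb <- ceiling(chrom_lengths / resolution)
  offs <- c(0, cumsum(nb))[seq_along(nb)]
  structure(
    list(
      chrom_names = as.character(chrom_names),
      chrom_lengths = chrom_lengths,
      resolution = resolution,
      n_bins_per_chrom = as.integer(nb),
      bin_offset = as.integer(offs),
      excluded_chroms = intersect(excluded_chroms, chrom_names)
    ),
    class = "sc_genome"
  )
}

#' @export
print.sc_genome <- function(x, ...) {
  cat(sprintf(
    "<sc_genome> %d chromosomes, %s bp resolution, %d global bins\n",
    length(x$chrom_names), format(x$resolution, big.mark = ","), n_bins(x)
  ))
  invisible(x)
}

#' Total number of global bins
#' @param genome an `sc_genome`.
#' @return integer bin count B.
#' @export
n_bins <- function(genome) {
  stopifnot(inherits(genome, "sc_genome"))
  sum(genome$n_bins_per_chrom)
}

#' Rebin a genome at a different resolution
#' @param genome an `sc_genome`.
#' @param resolution new bin width in bp.
#' @return an `sc_genome` sharing chromosomes but binned at `resolution`.
#' @export
with_resolution <- function(genome, resolution) {
  sc_genome(genome$chrom_names, genome$chrom_lengths, resolution,
            genome$excluded_chroms)
}

#' Map genomic coordinates to global bin indices
#'
#' Pairs-format positions are 1-based; bins are 0-based half-open internally,
#' so `bin = floor((pos - 1) / resolution)` within the chromosome, then offset
#' to the global index (1-based).
#'
#' @param genome an `sc_genome`.
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @return integer vector of global bin indices (NA for unknown chromosomes).
#' @export
bin_index <- function(genome, chrom, pos) {
  ci <- match(chrom, genome$chrom_names)
  local_bin <- floor((pos - 1) / genome$resolution)
  bad <- !is.na(ci) & (pos < 1 | local_bin >= genome$n_bins_per_chrom[ci])
  if (any(bad)) stop("position outside chromosome bounds")
  as.integer(genome$bin_offset[ci] + local_bin + 1L)
}

#' Tibble describing every global bin
#' @param genome an `sc_genome`.
#' @return a tibble with `bin`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
genome_bins <- function(genome) {
  stopifnot(inherits(genome, "sc_genome"))
  chrom <- rep(genome$chrom_names, genome$n_bins_per_chrom)
  local <- unlist(lapply(genome$n_bins_per_chrom, seq_len)) - 1L
  len <- rep(genome$chrom_lengths, genome$n_bins_per_chrom)
  tibble::tibble(
    bin = seq_along(chrom),
    chrom = chrom,
    start = local * genome$resolution + 1,
    end = pmin((local + 1) * genome$resolution, len)
  )
}

#' Chromosome of each global bin
#' @param genome an `sc_genome`.
#' @return character vector of length `n_bins(genome)`.
#' @export
bin_chrom <- function(genome) {
  rep(genome$chrom_names, genome$n_bins_per_chrom)
}

#' Read a two-column chromosome-sizes file
#' @param path chrom.sizes text file (chrom, length).
#' @inheritParams sc_genome
#' @return an `sc_genome`.
#' @export
read_chrom_sizes <- function(path, resolution = 1e6, excluded_chroms = "chrY") {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  sc_genome(df$chrom, df$length, resolution, excluded_chroms)
}

#' Write a chromosome-sizes file
#' @param genome an `sc_genome`.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(genome$chrom_names, format(genome$chrom_lengths, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Convenience constructor for hg38 at 1 Mb (chr1..chr22, chrX)
#'
#' Used for shape audits: yields 3,044 global bins at 1 Mb.
#' @param resolution bin width in bp.
#' @return an `sc_genome`.
#' @export
hg38_genome <- function(resolution = 1e6) {
  lens <- c(
    chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
    chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468, chrX = 156040895
  )
  sc_genome(names(lens), unname(lens), resolution)
}
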