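#' Construct a genome build table
#'
#' A genome build records, per chromosome, its length and centromere
#' interval. Telomeres are implied at coordinates 0 and `length`. All
#' science functions (`compute_gi_score()`, `count_lga()`, ...) take the
#' build as an explicit argument, so analyses are never tied to a single
#' reference.
#'
#' Coordinates are 0-based half-open throughout the package; input formats
#' that use 1-based inclusive coordinates (the SEG dialect) are converted
#' on read.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Chromosome lengths in bp, all `> 0`.
#' @param cen_start,cen_end Centromere interval per chromosome, 0-based
#'   half-open, strictly inside `(0, length)`.
#' @return A tibble of class `hrd_build` with columns `chrom`, `length`,
#'   `cen_start`, `cen_end`.
#' @seealso [default_build()]
#' @examples
#' genome_build("chr1", 2e8, 9e7, 1e8)
#' @export
genome_build <- function(chrom, length, cen_start, cen_end) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom) > 0) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (any(cen_start <= 0 | cen_end >= length | cen_start >= cen_end)) {
    stop("centromere interval must lie strictly inside (0, length)", call. = FALSE)
  }
  structure(
    tibble::tibble(
      chrom = chrom,
      length = as.numeric(length),
      cen_start = as.numeric(cen_start),
      cen_end = as.numeric(cen_end)
    ),
    class = c("hrd_build", class(tibble::tibble()))
  )
}

#' Default human-like genome build (22 autosomes)
#'
#' Autosome lengths and approximate centromere intervals matching the
#' GRCh37 assembly. Sex chromosomes are excluded: minor-allele semantics
#' differ there and scar scoring conventionally uses autosomes only.
#'
#' @return An `hrd_build` tibble with 22 rows.
#' @examples
#' default_build()
#' @export
default_build <- function() {
  lens <- c(
    249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
    159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
    115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
    59128983, 63025520, 48129895, 51304566
  )
  cen_start <- c(
    121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
    58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
    16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
    24681782, 26369569, 11288129, 13000000
  )
  cen_end <- c(
    124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
    61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
    19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
    27681782, 29369569, 14288129, 16000000
  )
  genome_build(paste0("chr", 1:22), lens, cen_start, cen_end)
}

#' Normalize chromosome names against a build
#'
#' Accepts both `"chr1"` and `"1"` spellings and maps them onto the
#' build's own naming. Unknown chromosomes raise an error.
#'
#' @param chrom Character vector of chromosome names.
#' @param build An `hrd_build`.
#' @return Character vector in the build's naming.
#' @export
normalize_chrom <- function(chrom, build) {
  chrom <- as.character(chrom)
  bare_build <- sub("^chr", "", build$chrom)
  bare_in <- sub("^chr", "", chrom)
  idx <- match(bare_in, bare_build)
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  build$chrom[idx]
}

# Split a build into chromosome arms: one row per arm with arm_start/arm_end
# (0-based half-open, centromere excluded).
build_arms <- function(build) {
  dplyr::bind_rows(
    tibble::tibble(
      chrom = build$chrom, arm = "p",
      arm_start = 0, arm_end = build$cen_start
    ),
    tibble::tibble(
      chrom = build$chrom, arm = "q",
      arm_start = build$cen_end, arm_end = build$length
    )
  ) |>
    dplyr::arrange(match(.data$chrom, build$chrom), .data$arm)
}

build_row <- function(build, chrom) {
  i <- match(chrom, build$chrom)
  if (is.na(i)) stop("chromosome not in build: ", chrom, call. = FALSE)
  build[i, ]
}
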