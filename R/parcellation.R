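#' Construct a bilaterally symmetric parcellation
#'
#' A parcellation assigns every region a label, a hemisphere, and the index of
#' its homologous region in the opposite hemisphere. Region order is the
#' matrix row/column order of every connectome analysed against it.
#'
#' @param label character vector of unique region labels.
#' @param hemisphere character vector, each element `"left"` or `"right"`.
#' @param homolog integer vector; `homolog[u]` is the index of region `u`'s
#'   contralateral homolog.
#'
#' @details The homolog map must be an involution (`homolog[homolog[u]] == u`)
#'   that crosses hemispheres, and the two hemispheres must contain the same
#'   number of regions. These properties are what make bilateral pairing of
#'   intra-hemispheric connections well defined.
#'
#' @return An object of class `parcellation`.
#' @export
#' @examples
#' parcellation(c("L1", "L2", "R1", "R2"),
#'              c("left", "left", "right", "right"),
#'              c(3L, 4L, 1L, 2L))
parcellation <- function(label, hemisphere, homolog) {
  n <- length(label)
  if (length(hemisphere) != n || length(homolog) != n)
    abort_validation("label, hemisphere and homolog must have equal length")
  if (anyDuplicated(label))
    abort_validation("region labels must be unique")
  if (!all(hemisphere %in% c("left", "right")))
    abort_validation("hemisphere entries must be 'left' or 'right'")
  if (sum(hemisphere == "left") != sum(hemisphere == "right"))
    abort_validation("unequal number of left (%d) and right (%d) regions",
                     sum(hemisphere == "left"), sum(hemisphere == "right"))
  homolog <- as.integer(homolog)
  if (anyNA(homolog) || any(homolog < 1L) || any(homolog > n))
    abort_validation("homolog indices must be in 1..%d", n)
  if (!identical(homolog[homolog], seq_len(n)))
    abort_validation("homolog map is not an involution")
  if (any(hemisphere[homolog] == hemisphere))
    abort_validation("homolog map must cross hemispheres")
  structure(
    list(label = as.character(label), hemisphere = hemisphere,
         homolog = homolog),
    class = "parcellation"
  )
}

#' Number of regions in a parcellation
#' @param parc a [parcellation()].
#' @return Integer region count.
#' @export
n_regions <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  length(parc$label)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d regions (%d per hemisphere)\n",
              n_regions(x), sum(x$hemisphere == "left")))
  invisible(x)
}

#' Read a parcellation table
#'
#' Reads a CSV with columns `label`, `hemisphere` and `homolog_label`
#' (the label of each region's contralateral homolog). Region order is the
#' file's row order.
#'
#' @param path path to the CSV file.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path))
    abort_validation("parcellation file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  required <- c("label", "hemisphere", "homolog_label")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    abort_validation("parcellation file missing column(s): %s",
                     paste(missing, collapse = ", "))
  homolog <- match(tab$homolog_label, tab$label)
  if (anyNA(homolog))
    abort_validation("homolog_label refers to unknown region(s): %s",
                     paste(unique(tab$homolog_label[is.na(homolog)]),
                           collapse = ", "))
  parcellation(tab$label, tolower(tab$hemisphere), homolog)
}

#' Write a parcellation table
#'
#' Inverse of [read_parcellation()].
#'
#' @param parc a [parcellation()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  tab <- data.frame(label = parc$label, hemisphere = parc$hemisphere,
                    homolog_label = parc$label[parc$homolog])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
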