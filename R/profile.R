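#' Glycan profiles as tibbles
#'
#' A glycan profile is the relative-abundance distribution over glycan
#' species indexed `k = 1..Ns` along the reaction line graph. It is stored
#' as a tibble with columns `index` (contiguous 1-based integers) and
#' `abundance` (nonnegative reals), carrying class `glycan_profile`.
#'
#' @param abundance Nonnegative numeric vector of abundances for
#'   `k = 1..length(abundance)`.
#' @param normalize If `TRUE`, rescale abundances to sum to 1.
#' @return A `glycan_profile` tibble.
#' @examples
#' p <- glycan_profile(c(2, 1, 1), normalize = TRUE)
#' profile_entropy(p)
#' @export
glycan_profile <- function(abundance, normalize = FALSE) {
  abundance <- as.numeric(abundance)
  if (length(abundance) < 1) abort("empty abundance vector.")
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    abort("abundances must be finite and nonnegative.")
  }
  if (normalize) {
    tot <- sum(abundance)
    if (tot <= 0) abort("cannot normalize an all-zero profile.")
    abundance <- abundance / tot
  }
  structure(
    tibble::tibble(index = seq_along(abundance), abundance = abundance),
    class = c("glycan_profile", class(tibble::tibble()))
  )
}

#' Normalize a glycan profile to a probability vector
#'
#' @param profile A `glycan_profile` or two-column data frame.
#' @return A normalized `glycan_profile` (abundances sum to 1).
#' @export
normalize_profile <- function(profile) {
  glycan_profile(profile_vec(profile), normalize = TRUE)
}

# extract the abundance vector, checking the contiguous 1..Ns contract
profile_vec <- function(profile) {
  if (is.numeric(profile)) {
    v <- as.numeric(profile)
  } else if (is.data.frame(profile)) {
    if (!all(c("index", "abundance") %in% names(profile))) {
      abort("profile data frame needs `index` and `abundance` columns.")
    }
    o <- order(profile$index)
    idx <- profile$index[o]
    if (!identical(as.integer(idx), seq_along(idx))) {
      abort("profile indices must be contiguous 1-based integers.")
    }
    v <- as.numeric(profile$abundance[o])
  } else {
    abort("profile must be a numeric vector or a data frame.")
  }
  if (any(!is.finite(v)) || any(v < 0)) abort("negative or non-finite abundance.")
  v
}

is_normalized <- function(profile, tol = 1e-8) {
  abs(sum(profile_vec(profile)) - 1) <= tol
}

assert_normalized <- function(profile, arg = "profile") {
  if (!is_normalized(profile)) {
    abort(paste0("`", arg, "` must be normalized (abundances summing to 1); ",
                 "use normalize_profile()."))
  }
  invisible(TRUE)
}

#' Read a glycan profile from a tab-separated file
#'
#' Accepts the package's profile format (optional header line
#' `# glycan_profile Ns=<int> normalized=<bool>` followed by
#' `index<TAB>abundance`) as well as headerless two-column spectra whose
#' first column is an arbitrary increasing coordinate such as m/z; in the
#' latter case rows are rank-ordered onto indices `1..Ns`.
#'
#' @param path File path.
#' @param normalize Normalize abundances to sum to 1 after reading.
#' @return A `glycan_profile` tibble.
#' @export
read_glycan_profile <- function(path, normalize = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty profile file: ", path))
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0) abort(paste0("no data rows in profile file: ", path))
  parts <- strsplit(lines, "[\t ]+")
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad)) abort("each data row needs two columns: index/coordinate and abundance.")
  coord <- as.numeric(vapply(parts, `[`, character(1), 1))
  abun <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (any(is.na(coord)) || any(is.na(abun))) abort("non-numeric entries in profile file.")
  if (any(abun < 0)) abort("negative abundance in profile file.")
  o <- order(coord)
  coord <- coord[o]; abun <- abun[o]
  looks_indexed <- all(abs(coord - round(coord)) < 1e-9) &&
    identical(as.integer(round(coord)), seq_along(coord))
  if (!looks_indexed && all(abs(coord - round(coord)) < 1e-9) &&
      min(coord) >= 1 && !anyDuplicated(round(coord)) &&
      max(coord) <= 5 * length(coord)) {
    # integer indices with gaps: the contiguity contract is violated
    abort("profile indices must be contiguous 1-based integers.")
  }
  glycan_profile(abun, normalize = normalize)
}

#' Write a glycan profile as a tab-separated file
#'
#' @param profile A `glycan_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_glycan_profile <- function(profile, path) {
  v <- profile_vec(profile)
  header <- sprintf("# glycan_profile Ns=%d normalized=%s", length(v),
                    tolower(as.character(is_normalized(profile))))
  body <- sprintf("%d\t%s", seq_along(v), formatC(v, format = "g", digits = 17))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @method autoplot glycan_profile
#' @export
autoplot.glycan_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$abundance)) +
    ggplot2::geom_col(width = 1, fill = "steelblue4") +
    ggplot2::labs(x = "glycan index k", y = "abundance") +
    ggplot2::theme_minimal()
}
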