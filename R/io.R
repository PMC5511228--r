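#' Read long-format occurrence records
#'
#' Reads a delimited text file of occurrence records, one row per record of a
#' species on an island in a census period. Duplicate (species, island,
#' period) triples are collapsed to a single record; the number of raw and
#' deduplicated records is reported via [message()].
#'
#' @param path path to a delimited text file with columns for species, island
#'   and period (matched by name, see `columns`, or by position 1:3 when the
#'   names are absent).
#' @param sep field delimiter; `","` by default, `"\t"` accepted.
#' @param columns character vector of length 3 naming the species, island and
#'   period columns, in that order.
#' @param quiet suppress the record-count message.
#' @return a data.frame of class `occurrence_table` with character columns
#'   `species`, `island`, `period`, deduplicated.
#' @seealso [read_islands()], [read_traits()], [validate_dataset()],
#'   [build_incidence()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("species,island,period", "sp1,i1,P1", "sp1,i1,P1",
#'              "sp2,i1,P2"), tf)
#' occ <- read_occurrences(tf)
#' nrow(occ) # 2: the duplicate row collapses
#' @export
read_occurrences <- function(path, sep = ",", columns = c("species", "island", "period"),
                             quiet = FALSE) {
  raw <- read_table_checked(path, sep)
  df <- resolve_columns(raw, columns, what = "occurrence")
  names(df) <- c("species", "island", "period")
  df[] <- lapply(df, function(x) trimws(as.character(x)))
  n_raw <- nrow(df)
  df <- unique(df)
  rownames(df) <- NULL
  if (!quiet) {
    message(sprintf("read %d occurrence records (%d after collapsing duplicates)",
                    n_raw, nrow(df)))
  }
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' Read the island attribute table
#'
#' @param path delimited text file with columns `island` and `area_km2`
#'   (matched by name, or positions 1:2).
#' @param sep field delimiter.
#' @return data.frame with character `island` and numeric `area_km2`.
#' @export
read_islands <- function(path, sep = ",") {
  raw <- read_table_checked(path, sep)
  df <- resolve_columns(raw, c("island", "area_km2"), what = "island")
  names(df) <- c("island", "area_km2")
  df$island <- trimws(as.character(df$island))
  df$area_km2 <- as.numeric(df$area_km2)
  if (anyDuplicated(df$island)) {
    stop("duplicate island ids in island table: ",
         paste(unique(df$island[duplicated(df$island)]), collapse = ", "))
  }
  if (any(!is.finite(df$area_km2)) || any(df$area_km2 <= 0)) {
    stop("island areas must be strictly positive (km^2)")
  }
  rownames(df) <- NULL
  df
}

#' Read the species trait table
#'
#' Each species carries exactly one origin (`native` or `alien`) and one
#' functional type (`AH` annual herbaceous, `PH` perennial herbaceous, `W`
#' woody).
#'
#' @param path delimited text file with columns `species`, `origin`,
#'   `functional_type` (matched by name, or positions 1:3).
#' @param sep field delimiter.
#' @return data.frame with character columns `species`, `origin`,
#'   `functional_type`.
#' @export
read_traits <- function(path, sep = ",") {
  raw <- read_table_checked(path, sep)
  df <- resolve_columns(raw, c("species", "origin", "functional_type"),
                        what = "trait")
  names(df) <- c("species", "origin", "functional_type")
  df[] <- lapply(df, function(x) trimws(as.character(x)))
  if (anyDuplicated(df$species)) {
    stop("duplicate species ids in trait table")
  }
  bad <- setdiff(unique(df$origin), c("native", "alien"))
  if (length(bad)) stop("unknown origin values: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$functional_type), c("AH", "PH", "W"))
  if (length(bad)) stop("unknown functional types: ", paste(bad, collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Check referential integrity of an occurrence dataset
#'
#' Verifies that every island id in the occurrence table appears in the
#' island table and every species id appears in the trait table. In strict
#' mode (the default) a violation is an error; in lenient mode offending ids
#' are attached as attributes `unknown_islands` / `unknown_species` and a
#' warning is raised.
#'
#' @param occ occurrence table ([read_occurrences()]).
#' @param islands island table ([read_islands()]).
#' @param traits trait table ([read_traits()]), or `NULL` to skip the
#'   species check.
#' @param strict logical; error (`TRUE`) or warn-and-flag (`FALSE`).
#' @return `occ`, invisibly, possibly with flag attributes in lenient mode.
#' @export
validate_dataset <- function(occ, islands, traits = NULL, strict = TRUE) {
  bad_isl <- setdiff(unique(occ$island), islands$island)
  bad_sp <- if (is.null(traits)) character(0) else
    setdiff(unique(occ$species), traits$species)
  if (strict) {
    if (length(bad_isl)) {
      stop("occurrence records refer to unknown islands: ",
           paste(utils::head(bad_isl, 5), collapse = ", "))
    }
    if (length(bad_sp)) {
      stop("occurrence records refer to species absent from the trait table: ",
           paste(utils::head(bad_sp, 5), collapse = ", "))
    }
  } else {
    if (length(bad_isl) || length(bad_sp)) {
      warning(sprintf("%d unknown island id(s), %d unknown species id(s) flagged",
                      length(bad_isl), length(bad_sp)))
    }
    attr(occ, "unknown_islands") <- bad_isl
    attr(occ, "unknown_species") <- bad_sp
  }
  invisible(occ)
}

#' Write an occurrence table as delimited text
#'
#' Inverse of [read_occurrences()]: round-tripping preserves the record set.
#'
#' @param occ occurrence table.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, sep = ",") {
  utils::write.table(as.data.frame(occ)[c("species", "island", "period")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

read_table_checked <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("no data rows in: ", path)
  df
}

# Match required columns by name, falling back to position when all names
# are absent (headerless-style files read with made-up names still error).
resolve_columns <- function(df, wanted, what) {
  hit <- match(wanted, names(df))
  if (all(!is.na(hit))) return(df[, hit, drop = FALSE])
  if (ncol(df) >= length(wanted) && all(is.na(hit))) {
    return(df[, seq_along(wanted), drop = FALSE])
  }
  stop(sprintf("%s table must provide columns %s (found: %s)", what,
               paste(wanted, collapse = ", "), paste(names(df), collapse = ", ")))
}
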