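#' EQ-5D-3L descriptive-system codes
#'
#' All 243 five-digit EQ-5D-3L health-state codes. Each digit is the level
#' (1 = no problems, 2 = some problems, 3 = extreme problems) on one of the
#' five dimensions: mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression.
#'
#' @return Character vector of length 243, sorted.
#' @export
#' @examples
#' head(eq5d_codes())
eq5d_codes <- function() {
  g <- expand.grid(ad = 1:3, pd = 1:3, ua = 1:3, sc = 1:3, mo = 1:3)
  sort(paste0(g$mo, g$sc, g$ua, g$pd, g$ad))
}

.EQ5D_DIMENSIONS <- c("MO", "SC", "UA", "PD", "AD")

.check_eq5d_code <- function(code) {
  if (length(code) != 1L || !is.character(code) || is.na(code))
    stop("EQ-5D-3L code must be a single character string", call. = FALSE)
  if (!grepl("^[123]{5}$", code)) {
    bad <- regmatches(code, regexpr("[^123]", code))
    detail <- if (length(bad) && nchar(code) == 5L)
      sprintf("contains invalid level '%s'", bad)
    else "must be 5 digits, each in 1-3"
    stop(sprintf("malformed EQ-5D-3L code '%s': %s", code, detail),
         call. = FALSE)
  }
  invisible(code)
}

#' Construct an EQ-5D-3L value set
#'
#' A value set maps each of the 243 EQ-5D-3L codes to a utility on the
#' dead = 0 / full health = 1 scale (values below 0 denote states worse
#' than death). The full-health code "11111" must score exactly 1 and no
#' score may exceed 1.
#'
#' @param scores Named numeric vector: names are the 243 codes, values the
#'   utilities.
#' @param name Label for the value set.
#' @return An object of class `eq5d_value_set`.
#' @seealso [value_set_from_decrements()], [read_value_set()],
#'   [synthetic_value_set()]
#' @export
value_set <- function(scores, name = "custom") {
  if (is.null(names(scores)))
    .fail_field("scores", "must be a named vector (names = EQ-5D-3L codes)")
  codes <- eq5d_codes()
  missing <- setdiff(codes, names(scores))
  if (length(missing))
    .fail_field("scores", sprintf("%d of 243 codes unresolved (first: %s)",
                                  length(missing), missing[1]))
  scores <- scores[codes]
  if (abs(scores[["11111"]] - 1) > 1e-12)
    .fail_field("scores", "full-health code 11111 must score exactly 1")
  if (any(scores > 1 + 1e-12))
    .fail_field("scores", "no score may exceed 1")
  structure(list(name = name, scores = scores), class = "eq5d_value_set")
}

#' Build a value set from additive dimension decrements
#'
#' Standard additive TTO-style scheme: the utility of a code is
#' 1 minus the sum of the per-dimension decrements for every dimension at
#' level 2 or 3 (level 1 contributes nothing).
#'
#' @param decrements Data frame with columns `dimension` (MO, SC, UA, PD,
#'   AD), `level` (2 or 3) and `decrement` (nonnegative).
#' @param name Label.
#' @return An `eq5d_value_set`.
#' @export
value_set_from_decrements <- function(decrements, name = "additive") {
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(decrements)))
    .fail_field("decrements", paste("needs columns", paste(need, collapse = ", ")))
  if (any(decrements$decrement < 0))
    .fail_field("decrement", "must be nonnegative")
  dec <- matrix(0, nrow = 3, ncol = 5,
                dimnames = list(1:3, .EQ5D_DIMENSIONS))
  for (i in seq_len(nrow(decrements))) {
    d <- decrements[i, ]
    if (!d$dimension %in% .EQ5D_DIMENSIONS)
      .fail_field("dimension", sprintf("unknown dimension '%s'", d$dimension))
    if (!d$level %in% 2:3)
      .fail_field("level", "must be 2 or 3")
    dec[as.character(d$level), d$dimension] <- d$decrement
  }
  codes <- eq5d_codes()
  lv <- matrix(as.integer(unlist(strsplit(codes, ""))),
               ncol = 5, byrow = TRUE)
  scores <- 1 - vapply(seq_along(codes), function(i)
    sum(dec[cbind(lv[i, ], seq_len(5))]), numeric(1))
  value_set(setNames(scores, codes), name = name)
}

#' Read a value set from a delimited text file
#'
#' Two formats are accepted and auto-detected from the header:
#' a full table with columns `code`, `score` (one row per health state), or
#' an additive coefficient scheme with columns `dimension`, `level`,
#' `decrement` (see [value_set_from_decrements()]).
#'
#' @param path Path to a tab- or comma-delimited text file with a header.
#' @param name Label; defaults to the file name.
#' @return An `eq5d_value_set`.
#' @export
read_value_set <- function(path, name = basename(path)) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (all(c("code", "score") %in% names(df))) {
    value_set(setNames(as.numeric(df$score), df$code), name = name)
  } else if (all(c("dimension", "level", "decrement") %in% names(df))) {
    df$level <- as.integer(df$level)
    df$decrement <- as.numeric(df$decrement)
    value_set_from_decrements(df, name = name)
  } else {
    stop("unrecognised value-set file: need columns code/score or ",
         "dimension/level/decrement", call. = FALSE)
  }
}

#' The bundled synthetic test value set
#'
#' A synthetic additive value set shipped for testing and examples. It is
#' NOT a published national tariff: real analyses should supply their
#' country's value set via [read_value_set()]. Its floor (code "33333")
#' is -0.200, emulating the worse-than-death range of typical TTO sets.
#'
#' @return An `eq5d_value_set`.
#' @export
#' @examples
#' vs <- synthetic_value_set()
#' score_eq5d("11111", vs)
synthetic_value_set <- function() {
  path <- system.file("extdata", "value_set_synthetic_test.tsv",
                      package = "rrmscea", mustWork = TRUE)
  read_value_set(path, name = "synthetic_test")
}

#' Score an EQ-5D-3L code against a value set
#'
#' @param code Five-character string, each character in 1-3.
#' @param vs An `eq5d_value_set`.
#' @return The utility value (numeric scalar, at most 1).
#' @export
#' @examples
#' score_eq5d("11111", synthetic_value_set())  # 1
score_eq5d <- function(code, vs) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  .check_eq5d_code(code)
  unname(vs$scores[[code]])
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat(sprintf("<eq5d_value_set '%s'>  243 codes, range [%.3f, %.3f]\n",
              x$name, min(x$scores), max(x$scores)))
  invisible(x)
}
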