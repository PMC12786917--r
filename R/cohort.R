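#' Read a questionnaire cohort from a delimited file
#'
#' Parses a CSV (or TSV) cohort file against a codebook. The header row must
#' consist of codebook `item_id`s (any order, any subset as long as
#' `patient_id` is present); unknown columns are rejected. Empty cells are
#' missing values. Booleans are coded `0`/`1`, categorical items as the
#' uppercase tokens of [codebook_levels()]. Every parsed record is validated
#' against the record invariants (see [validate_cohort()]) and any violation
#' aborts the read with a message naming row, column, and offending token.
#'
#' @param path Path to the delimited file (or a connection).
#' @param codebook Codebook data frame; defaults to [default_codebook()].
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return A cohort data frame with one row per patient and typed columns
#'   for every codebook item present in the file (missing columns are added
#'   as all-`NA` so downstream code can rely on the full schema).
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_spec(n_ems = 5, n_no_ems = 5))
#' f <- tempfile(fileext = ".csv")
#' write_cohort(coh, f)
#' coh2 <- read_cohort(f)
#' identical(dim(coh), dim(coh2))
read_cohort <- function(path, codebook = default_codebook(), sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  unknown <- setdiff(names(raw), codebook$item_id)
  if (length(unknown) > 0) {
    stop("unknown column(s) not in codebook: ", paste(unknown, collapse = ", "))
  }
  if (!"patient_id" %in% names(raw)) stop("column 'patient_id' is required")
  n <- nrow(raw)
  out <- empty_cohort(n, codebook)
  levels_by_item <- codebook_levels()

  parse_fail <- function(row, col, token, why) {
    stop(sprintf("row %d, column '%s': invalid value '%s' (%s)",
                 row, col, token, why), call. = FALSE)
  }
  parse_int <- function(x, col, lo, hi) {
    v <- rep(NA_integer_, length(x))
    present <- !is.na(x) & nzchar(x)
    suppressWarnings(num <- as.numeric(x[present]))
    bad <- which(is.na(num) | num != floor(num) | num < lo | num > hi)
    if (length(bad) > 0) {
      i <- which(present)[bad[1]]
      parse_fail(i, col, x[i], sprintf("expected integer in [%d,%d]", lo, hi))
    }
    v[present] <- as.integer(num)
    v
  }

  for (col in names(raw)) {
    kind <- codebook$value_kind[codebook$item_id == col]
    x <- raw[[col]]
    out[[col]] <- switch(
      kind,
      ID = ifelse(nzchar(x), x, NA_character_),
      LABEL = ,
      CATEGORICAL = {
        lv <- levels_by_item[[col]]
        v <- ifelse(nzchar(x), x, NA_character_)
        bad <- which(!is.na(v) & !v %in% lv)
        if (length(bad) > 0) {
          parse_fail(bad[1], col, v[bad[1]],
                     paste("expected one of", paste(lv, collapse = "/")))
        }
        v
      },
      BOOLEAN = {
        v <- rep(NA, n)
        present <- nzchar(x)
        bad <- which(present & !x %in% c("0", "1"))
        if (length(bad) > 0) parse_fail(bad[1], col, x[bad[1]], "expected 0 or 1")
        v[present] <- x[present] == "1"
        v
      },
      NRS_0_10 = parse_int(x, col, 0L, 10L),
      SENSORY_0_5 = parse_int(x, col, 0L, 5L),
      REAL = {
        v <- rep(NA_real_, n)
        present <- nzchar(x)
        suppressWarnings(num <- as.numeric(x[present]))
        bad <- which(is.na(num) | num < 0)
        if (length(bad) > 0) {
          i <- which(present)[bad[1]]
          parse_fail(i, col, x[i], "expected non-negative real")
        }
        v[present] <- num
        v
      },
      stop("unhandled value kind: ", kind)
    )
  }
  if (anyNA(out$patient_id)) stop("missing patient_id in row ",
                                  which(is.na(out$patient_id))[1])
  if (anyDuplicated(out$patient_id)) {
    stop("duplicate patient_id: ",
         out$patient_id[duplicated(out$patient_id)][1])
  }
  viol <- validate_cohort(out, codebook)
  if (nrow(viol) > 0) {
    stop(sprintf("record invariant violated for patient '%s', field '%s': %s",
                 viol$patient_id[1], viol$field[1], viol$message[1]),
         call. = FALSE)
  }
  out
}

#' Write a cohort to a delimited file
#'
#' Serialisation is the exact inverse of [read_cohort()]: booleans as
#' `0`/`1`, missing values as empty cells, categorical tokens verbatim.
#' Output is byte-stable for a fixed input.
#'
#' @inheritParams read_cohort
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, codebook = default_codebook(),
                         sep = ",") {
  cols <- intersect(codebook$item_id, names(cohort))
  ser <- lapply(cols, function(col) {
    kind <- codebook$value_kind[codebook$item_id == col]
    x <- cohort[[col]]
    s <- if (kind == "BOOLEAN") {
      ifelse(is.na(x), "", ifelse(x, "1", "0"))
    } else if (kind == "REAL") {
      ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE,
                                  drop0trailing = TRUE))
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
    if (any(grepl(sep, s, fixed = TRUE))) {
      stop("value in column '", col, "' contains the field delimiter")
    }
    s
  })
  names(ser) <- cols
  m <- do.call(cbind, ser)
  lines <- c(paste(cols, collapse = sep),
             if (nrow(cohort) > 0) apply(m, 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Validate record invariants
#'
#' Total check: never raises on a parseable cohort, returns one row per
#' violation instead. Rules checked per record:
#' * every NRS value, when present, is an integer in 0--10;
#' * every sensory item, when present, is an integer in 0--5;
#' * a symptom reported absent (`FALSE`) with a present NRS requires NRS 0;
#' * `label` and categorical items take only their allowed tokens.
#'
#' @inheritParams write_cohort
#' @return Data frame with columns `patient_id`, `field`, `rule`, `message`;
#'   zero rows iff every record satisfies all invariants.
#' @export
validate_cohort <- function(cohort, codebook = default_codebook()) {
  v <- list()
  add <- function(idx, field, rule, message) {
    if (length(idx) == 0) return()
    v[[length(v) + 1]] <<- data.frame(
      patient_id = as.character(cohort$patient_id[idx]),
      field = field, rule = rule, message = message,
      stringsAsFactors = FALSE)
  }
  rng <- function(cols, lo, hi, rule) {
    for (col in intersect(cols, names(cohort))) {
      x <- cohort[[col]]
      bad <- which(!is.na(x) & (x < lo | x > hi | x != floor(x)))
      add(bad, col, rule,
          sprintf("value %s outside integer range [%d,%d]", x[bad], lo, hi))
    }
  }
  rng(items_of_kind(codebook, "NRS_0_10"), 0L, 10L, "nrs_range")
  rng(items_of_kind(codebook, "SENSORY_0_5"), 0L, 5L, "sensory_range")

  pairs <- list(c("dysmenorrhea", "dysmenorrhea_nrs"), c("cpp", "cpp_nrs"),
                c("dysuria", "dysuria_nrs"), c("dyschezia", "dyschezia_nrs"),
                c("dyspareunia", "dyspareunia_nrs"))
  for (p in pairs) {
    if (!all(p %in% names(cohort))) next
    b <- cohort[[p[1]]]
    s <- cohort[[p[2]]]
    bad <- which(!is.na(b) & !b & !is.na(s) & s > 0)
    add(bad, p[2], "absent_symptom_nonzero_nrs",
        sprintf("'%s' is FALSE but '%s' is %s (must be 0 or missing)",
                p[1], p[2], s[bad]))
  }
  lv <- codebook_levels()
  for (col in intersect(names(lv), names(cohort))) {
    x <- cohort[[col]]
    bad <- which(!is.na(x) & !x %in% lv[[col]])
    add(bad, col, "unknown_token",
        sprintf("token '%s' not in {%s}", x[bad],
                paste(lv[[col]], collapse = ", ")))
  }
  if (length(v) == 0) {
    return(data.frame(patient_id = character(), field = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' An all-missing cohort skeleton
#'
#' @param n Number of rows.
#' @inheritParams read_cohort
#' @return Cohort data frame with `n` rows, every cell missing.
#' @export
empty_cohort <- function(n, codebook = default_codebook()) {
  cols <- lapply(codebook$value_kind, function(kind) {
    switch(kind,
           ID = , LABEL = , CATEGORICAL = rep(NA_character_, n),
           BOOLEAN = rep(NA, n),
           NRS_0_10 = , SENSORY_0_5 = rep(NA_integer_, n),
           REAL = rep(NA_real_, n))
  })
  names(cols) <- codebook$item_id
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}
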