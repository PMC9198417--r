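# Balanced four-way data: I units, each observed as a P x R matrix at T
# occasions. Internally stored as an I x T x P x R array; the user-facing
# exchange format is a long table with columns unit, time, row, col, value.

#' Construct a balanced four-way data object
#'
#' `fourway()` wraps an `I x T x P x R` array; `as_fourway()` builds the array
#' from a long-format data frame with one row per (unit, time, row level,
#' column level) cell. Units and row/column levels are ordered by first
#' appearance, times ascending.
#'
#' @param values A numeric array of dimension `I x T x P x R`.
#' @param unit_ids,time_ids,row_names,col_names Optional label vectors for the
#'   four dimensions.
#'
#' @return An object of class `"fourway"`.
#' @export
fourway <- function(values, unit_ids = NULL, time_ids = NULL,
                    row_names = NULL, col_names = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 4)
  if (!all(is.finite(values))) stop("all values must be finite", call. = FALSE)
  d <- dim(values)
  lbl <- function(x, n, prefix) {
    if (is.null(x)) paste0(prefix, seq_len(n)) else {
      stopifnot(length(x) == n)
      as.character(x)
    }
  }
  structure(
    list(values = values,
         unit_ids = lbl(unit_ids, d[1], "unit"),
         time_ids = if (is.null(time_ids)) seq_len(d[2]) else time_ids,
         row_names = lbl(row_names, d[3], "r"),
         col_names = lbl(col_names, d[4], "c")),
    class = "fourway"
  )
}

#' @param data A data frame in long format (or an existing `fourway` object,
#'   returned unchanged).
#' @param unit,time,row,col,value Column names (strings) identifying the unit,
#'   occasion, row level, column level and measurement.
#' @rdname fourway
#' @export
as_fourway <- function(data, unit = "unit", time = "time", row = "row",
                       col = "col", value = "value") {
  if (inherits(data, "fourway")) return(data)
  stopifnot(is.data.frame(data))
  cols <- c(unit, time, row, col, value)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  v <- data[[value]]
  if (!is.numeric(v)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
    stop("non-numeric value in column `", value, "` (row ", bad, ")", call. = FALSE)
  }
  if (any(!is.finite(v))) stop("all values must be finite", call. = FALSE)

  units <- unique(data[[unit]])
  times <- sort(unique(data[[time]]))
  rows <- unique(as.character(data[[row]]))
  colsv <- unique(as.character(data[[col]]))
  I <- length(units); T <- length(times); P <- length(rows); R <- length(colsv)

  iu <- match(data[[unit]], units)
  it <- match(data[[time]], times)
  ip <- match(as.character(data[[row]]), rows)
  ir <- match(as.character(data[[col]]), colsv)
  idx <- ((ir - 1L) * P + (ip - 1L)) * (I * T) + (it - 1L) * I + iu
  # the linear index above addresses arr[iu, it, ip, ir] in column-major order
  if (anyDuplicated(idx)) {
    d1 <- which(duplicated(idx))[1]
    stop("duplicate cell for unit `", data[[unit]][d1], "`, time `",
         data[[time]][d1], "`, levels (", data[[row]][d1], ", ",
         data[[col]][d1], ")", call. = FALSE)
  }
  if (nrow(data) != I * T * P * R) {
    have <- unique((it - 1L) * I + iu)
    counts <- table(factor((it - 1L) * I + iu, levels = seq_len(I * T)))
    bad <- which(counts < P * R)[1]
    bi <- (bad - 1L) %% I + 1L; bt <- (bad - 1L) %/% I + 1L
    stop("unbalanced data: unit `", units[bi], "` at time `", times[bt],
         "` has ", counts[bad], " of ", P * R, " cells", call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(I, T, P, R))
  arr[idx] <- as.numeric(v)
  fourway(arr, unit_ids = units, time_ids = times,
          row_names = rows, col_names = colsv)
}

#' @method as_tibble fourway
#' @export
as_tibble.fourway <- function(x, ...) {
  d <- dim(x$values)
  grid <- tidyr::expand_grid(
    col = x$col_names, row = x$row_names,
    time = x$time_ids, unit = x$unit_ids
  )
  # expand_grid varies the last column fastest, matching column-major order
  grid$value <- as.vector(x$values)
  tibble::as_tibble(grid[, c("unit", "time", "row", "col", "value")])
}

#' @export
print.fourway <- function(x, ...) {
  d <- dim(x$values)
  cat("<fourway> ", d[1], " units x ", d[2], " occasions of ",
      d[3], " x ", d[4], " matrices\n", sep = "")
  invisible(x)
}

#' @export
dim.fourway <- function(x) dim(x$values)

#' Extract one observation matrix
#'
#' @param x A `fourway` object.
#' @param i Unit index.
#' @param t Occasion index.
#' @return The `P x R` matrix observed for unit `i` at occasion `t`.
#' @export
obs_matrix <- function(x, i, t) {
  m <- x$values[i, t, , , drop = TRUE]
  matrix(m, dim(x$values)[3], dim(x$values)[4],
         dimnames = list(x$row_names, x$col_names))
}

#' Read and write four-way data as delimited long tables
#'
#' The on-disk format is a delimited text table with header columns
#' `unit`, `time`, `row`, `col`, `value`. Writing uses the shortest
#' representation that round-trips doubles, so a write/read cycle reproduces
#' the array bit-exactly.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return `read_fourway()` returns a `fourway` object; `write_fourway()`
#'   returns `path` invisibly.
#' @export
read_fourway <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(value = readr::col_character()))
  suppressWarnings(num <- as.numeric(tab$value))  # correctly-rounded strtod
  if (anyNA(num) && !anyNA(tab$value)) {
    stop("non-numeric value in column `value` (line ",
         which(is.na(num))[1] + 1L, ")", call. = FALSE)
  }
  tab$value <- num
  as_fourway(tab)
}

#' @param x A `fourway` object (or long data frame coercible to one).
#' @rdname read_fourway
#' @export
write_fourway <- function(x, path, delim = ",") {
  x <- as_fourway(x)
  tab <- as_tibble.fourway(x)
  tab$value <- sprintf("%.17g", tab$value)
  readr::write_delim(tab, path, delim = delim)
  invisible(path)
}

# Flatten to the N x (P*R) matrix used by the numerics: row n = (i-1)*T + t
# holds vec(X_it) (column-major, so column (r-1)*P + p).
flatten_fourway <- function(x) {
  d <- dim(x$values)
  m <- aperm(x$values, c(2, 1, 3, 4))  # (T, I, P, R); t varies fastest
  dim(m) <- c(d[2] * d[1], d[3] * d[4])
  m
}
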