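# Explicit embedded Runge-Kutta tableaux: construction, exact-rational
# validation, and JSON serialization.

# ---- exact rational helpers -------------------------------------------------
# Rationals are kept as c(num, den) in doubles; all intermediate products stay
# far below 2^53 for the tableaux handled here, so the arithmetic is exact.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

.rat_reduce <- function(r) {
  if (r[1] == 0) return(c(0, 1))
  g <- .gcd(r[1], r[2])
  r <- r / g
  if (r[2] < 0) r <- -r
  r
}

.rat_add <- function(x, y) {
  .rat_reduce(c(x[1] * y[2] + y[1] * x[2], x[2] * y[2]))
}

#' Parse a number given as a decimal or a "p/q" rational string
#'
#' Returns the exact rational representation `c(numerator, denominator)`.
#' Decimal strings are scaled by a power of ten, so they are exact too.
#' @noRd
.rat_parse <- function(x) {
  if (is.numeric(x)) x <- format(x, digits = 17, scientific = FALSE)
  x <- trimws(x)
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed rational string: ", x, call. = FALSE)
    num <- suppressWarnings(as.numeric(gsub(",", "", parts[1])))
    den <- suppressWarnings(as.numeric(gsub(",", "", parts[2])))
    if (is.na(num) || is.na(den) || den == 0) {
      stop("malformed rational string: ", x, call. = FALSE)
    }
    return(.rat_reduce(c(num, den)))
  }
  num <- suppressWarnings(as.numeric(x))
  if (is.na(num)) stop("malformed numeric string: ", x, call. = FALSE)
  if (num == round(num)) return(c(num, 1))
  digits <- nchar(sub("^-?[0-9]*\\.", "", x))
  .rat_reduce(c(round(num * 10^digits), 10^digits))
}

.rat_sum <- function(strings) {
  acc <- c(0, 1)
  for (s in strings) acc <- .rat_add(acc, .rat_parse(s))
  acc
}

.num_from_string <- function(x) {
  r <- .rat_parse(x)
  r[1] / r[2]
}

# ---- tableau construction ---------------------------------------------------

#' Construct an explicit embedded Runge-Kutta Butcher tableau
#'
#' An embedded pair is specified by node fractions `c`, a strictly
#' lower-triangular stage coefficient matrix `a`, and two weight vectors:
#' `b_high` (the propagating solution, order `order_high`) and `b_low` (the
#' embedded solution, order `order_low`) whose difference estimates the local
#' truncation error. Entries may be supplied as numerics or as strings, in
#' which case `"p/q"` rational notation is parsed exactly and retained for
#' exact validation of the order-independent consistency conditions.
#'
#' @param c Node fractions, length `s`.
#' @param a Stage coefficient matrix, `s x s`, strictly lower triangular.
#' @param b_high Propagating weights, length `s`.
#' @param b_low Embedded weights, length `s`.
#' @param order_high Order of the propagating solution.
#' @param order_low Order of the embedded solution.
#' @param name Human-readable identifier.
#' @return An object of class `butcher_tableau`.
#' @seealso [rk_dp54()], [validate_tableau()], [read_tableau()]
#' @export
#' @examples
#' tab <- rk_dp54()
#' nrow(validate_tableau(tab)) == 0
butcher_tableau <- function(c, a, b_high, b_low, order_high, order_low,
                            name = "custom") {
  if (is.list(a)) {
    a <- do.call(rbind, lapply(a, function(row) {
      if (is.list(row)) unlist(row) else row
    }))
  }
  char_input <- is.character(c) || is.character(a) ||
    is.character(b_high) || is.character(b_low)
  strings <- NULL
  if (char_input) {
    strings <- list(c = as.character(c), a = matrix(as.character(a), nrow(a)),
                    b_high = as.character(b_high), b_low = as.character(b_low))
    c <- vapply(strings$c, .num_from_string, numeric(1), USE.NAMES = FALSE)
    a <- apply(strings$a, c(1, 2), .num_from_string)
    b_high <- vapply(strings$b_high, .num_from_string, numeric(1), USE.NAMES = FALSE)
    b_low <- vapply(strings$b_low, .num_from_string, numeric(1), USE.NAMES = FALSE)
  }
  s <- length(c)
  if (!is.matrix(a) || nrow(a) != s || ncol(a) != s) {
    stop(structure(class = c("kinlearn_structure_error", "error", "condition"),
                   list(message = sprintf(
                     "stage matrix must be %d x %d to match %d nodes", s, s, s),
                     call = sys.call(-1))))
  }
  if (length(b_high) != s || length(b_low) != s) {
    stop(structure(class = c("kinlearn_structure_error", "error", "condition"),
                   list(message = "weight vectors must have one entry per stage",
                        call = sys.call(-1))))
  }
  structure(
    list(stages = s, c = as.numeric(c), a = unname(a),
         b_high = as.numeric(b_high), b_low = as.numeric(b_low),
         order_high = as.integer(order_high), order_low = as.integer(order_low),
         name = name, strings = strings),
    class = "butcher_tableau")
}

#' @export
print.butcher_tableau <- function(x, ...) {
  cat(sprintf("Embedded Runge-Kutta tableau '%s': %d stages, orders %d(%d)\n",
              x$name, x$stages, x$order_high, x$order_low))
  invisible(x)
}

#' The canonical Dormand-Prince 5(4) embedded pair
#'
#' Seven stages; the propagating solution has order 5, the embedded solution
#' order 4. Coefficients are stored as exact rationals so the consistency
#' conditions (`sum(b) = 1`, row-sum condition) validate exactly.
#'
#' @return A `butcher_tableau`.
#' @export
rk_dp54 <- function() {
  c_str <- c("0", "1/5", "3/10", "4/5", "8/9", "1", "1")
  a_str <- matrix("0", 7, 7)
  a_str[2, 1] <- "1/5"
  a_str[3, 1:2] <- c("3/40", "9/40")
  a_str[4, 1:3] <- c("44/45", "-56/15", "32/9")
  a_str[5, 1:4] <- c("19372/6561", "-25360/2187", "64448/6561", "-212/729")
  a_str[6, 1:5] <- c("9017/3168", "-355/33", "46732/5247", "49/176",
                     "-5103/18656")
  a_str[7, 1:6] <- c("35/384", "0", "500/1113", "125/192", "-2187/6784",
                     "11/84")
  b_high <- c("35/384", "0", "500/1113", "125/192", "-2187/6784", "11/84", "0")
  b_low <- c("5179/57600", "0", "7571/16695", "393/640", "-92097/339200",
             "187/2100", "1/40")
  butcher_tableau(c_str, a_str, b_high, b_low, order_high = 5L,
                  order_low = 4L, name = "dormand-prince-5(4)")
}

# ---- validation -------------------------------------------------------------

.violation <- function(check, stage, residual, message) {
  data.frame(check = check, stage = stage, residual = residual,
             message = message, stringsAsFactors = FALSE)
}

#' Validate an embedded Runge-Kutta tableau
#'
#' Checks the structural invariants of an explicit embedded pair:
#' explicitness (strictly lower-triangular `a`), consistency of both weight
#' vectors (`sum(b) = 1`), the row-sum condition `c[i] = sum(a[i, ])`, sane
#' distinct orders, and a non-degenerate embedded error estimator
#' (`b_high != b_low`). When the tableau was built from rational strings the
#' weight and row sums are checked with exact rational arithmetic; otherwise
#' a `1e-12` numeric tolerance is used.
#'
#' @param tableau A `butcher_tableau`.
#' @param tol Numeric tolerance for the consistency checks when no exact
#'   rational representation is available.
#' @return A data frame of violations with columns `check`, `stage`,
#'   `residual`, `message`; zero rows when the tableau is valid.
#' @export
validate_tableau <- function(tableau, tol = 1e-12) {
  if (!inherits(tableau, "butcher_tableau")) {
    stop(structure(class = c("kinlearn_structure_error", "error", "condition"),
                   list(message = "not a butcher_tableau object", call = NULL)))
  }
  s <- tableau$stages
  v <- .violation(character(), integer(), numeric(), character())

  # explicitness: a[i, j] = 0 for j >= i
  for (i in seq_len(s)) {
    for (j in i:s) {
      if (tableau$a[i, j] != 0) {
        v <- rbind(v, .violation("explicitness", i, abs(tableau$a[i, j]),
          sprintf("a[%d,%d] = %g must be zero for an explicit method",
                  i, j, tableau$a[i, j])))
      }
    }
  }

  exact <- !is.null(tableau$strings)
  sum_check <- function(strings, values) {
    if (exact) {
      r <- .rat_sum(strings)
      list(residual = abs(r[1] / r[2] - 1), ok = (r[1] == r[2]))
    } else {
      res <- abs(sum(values) - 1)
      list(residual = res, ok = res <= tol)
    }
  }

  bh <- sum_check(if (exact) tableau$strings$b_high else NULL, tableau$b_high)
  if (!bh$ok) {
    v <- rbind(v, .violation("weight_consistency", NA_integer_, bh$residual,
      sprintf("sum(b_high) != 1 (residual %.3g)", bh$residual)))
  }
  bl <- sum_check(if (exact) tableau$strings$b_low else NULL, tableau$b_low)
  if (!bl$ok) {
    v <- rbind(v, .violation("weight_consistency", NA_integer_, bl$residual,
      sprintf("sum(b_low) != 1 (residual %.3g)", bl$residual)))
  }

  # row-sum condition: c[i] = sum_j a[i, j]
  for (i in seq_len(s)) {
    if (exact) {
      target <- .rat_parse(tableau$strings$c[i])
      rowsum <- .rat_sum(tableau$strings$a[i, ])
      ok <- rowsum[1] * target[2] == target[1] * rowsum[2]
      residual <- abs(rowsum[1] / rowsum[2] - target[1] / target[2])
    } else {
      residual <- abs(sum(tableau$a[i, ]) - tableau$c[i])
      ok <- residual <= tol
    }
    if (!ok) {
      v <- rbind(v, .violation("row_sum", i, residual,
        sprintf("c[%d] != sum(a[%d, ]) (residual %.3g)", i, i, residual)))
    }
  }

  if (tableau$order_high < 1 || tableau$order_low < 1) {
    v <- rbind(v, .violation("orders", NA_integer_, NA_real_,
                             "both orders must be >= 1"))
  }
  if (tableau$order_high == tableau$order_low) {
    v <- rbind(v, .violation("orders", NA_integer_, 0,
      "order_high must differ from order_low for an embedded pair"))
  }
  if (all(tableau$b_high == tableau$b_low)) {
    v <- rbind(v, .violation("degenerate_embedded", NA_integer_, 0,
      paste("b_high and b_low are identical: the embedded error estimator is",
            "degenerate and the claimed order difference is unverifiable")))
  }
  v
}

# ---- JSON i/o ---------------------------------------------------------------

#' Read an embedded tableau from a JSON file
#'
#' Expects an object with fields `name`, `stages`, `c`, `a` (matrix as list of
#' rows), `b_high`, `b_low`, `order_high`, `order_low`. Numeric entries may be
#' plain numbers or strings in `"p/q"` rational notation (parsed exactly).
#'
#' @param path Path to the JSON file.
#' @return A `butcher_tableau`.
#' @export
read_tableau <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("c", "a", "b_high", "b_low", "order_high", "order_low")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop(structure(class = c("kinlearn_structure_error", "error", "condition"),
                   list(message = paste("tableau file missing fields:",
                                        paste(missing, collapse = ", ")),
                        call = NULL)))
  }
  a <- obj$a
  if (is.list(a)) a <- do.call(rbind, a)
  if (!is.matrix(a)) a <- matrix(a, nrow = length(obj$c))
  tab <- butcher_tableau(obj$c, a, obj$b_high, obj$b_low,
                         order_high = obj$order_high,
                         order_low = obj$order_low,
                         name = if (is.null(obj$name)) basename(path) else obj$name)
  if (!is.null(obj$stages) && obj$stages != tab$stages) {
    stop(structure(class = c("kinlearn_structure_error", "error", "condition"),
                   list(message = "declared stage count disagrees with c length",
                        call = NULL)))
  }
  tab
}

#' Write an embedded tableau to JSON
#'
#' Rational string coefficients are preserved when present so the file
#' round-trips exactly.
#'
#' @param tableau A `butcher_tableau`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tableau <- function(tableau, path) {
  use_str <- !is.null(tableau$strings)
  obj <- list(
    name = tableau$name,
    stages = tableau$stages,
    c = if (use_str) tableau$strings$c else tableau$c,
    a = if (use_str) {
      lapply(seq_len(tableau$stages), function(i) tableau$strings$a[i, ])
    } else {
      lapply(seq_len(tableau$stages), function(i) tableau$a[i, ])
    },
    b_high = if (use_str) tableau$strings$b_high else tableau$b_high,
    b_low = if (use_str) tableau$strings$b_low else tableau$b_low,
    order_high = tableau$order_high,
    order_low = tableau$order_low)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
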