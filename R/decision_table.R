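#' Construct a decision table
#'
#' A decision table is a tibble of `n` samples by `m` continuous conditional
#' attributes plus one categorical decision column. The decision column name
#' is stored as an attribute so downstream verbs (neighborhoods, entropies,
#' reduction) do not need it respecified. Decision classes are ordered by
#' first appearance in the decision column.
#'
#' @param data A data frame with at least one numeric attribute column and a
#'   decision column.
#' @param decision Name of the decision column. Defaults to the last column.
#' @return A tibble of class `decision_table` with attribute `decision`.
#' @examples
#' dt <- decision_table(data.frame(a = c(0, 1), b = c(1, 0), d = c("Y", "N")))
#' attr(dt, "decision")
#' @export
decision_table <- function(data, decision = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 1L || ncol(data) < 2L) {
    stop("a decision table needs at least 1 sample and 1 attribute plus a decision column",
         call. = FALSE)
  }
  decision <- decision %||% names(data)[ncol(data)]
  if (!decision %in% names(data)) {
    stop("decision column '", decision, "' not found in data", call. = FALSE)
  }
  attrs <- setdiff(names(data), decision)
  for (a in attrs) {
    if (!is.numeric(data[[a]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(data[[a]])))) &
                     !is.na(data[[a]]))
      stop("attribute column '", a, "' is not numeric",
           if (length(bad)) paste0(" (first offending row: ", bad[1L], ")") else "",
           call. = FALSE)
    }
    if (anyNA(data[[a]])) {
      stop("attribute column '", a, "' contains missing values (row ",
           which(is.na(data[[a]]))[1L], ")", call. = FALSE)
    }
  }
  y <- data[[decision]]
  if (anyNA(y)) {
    stop("decision column '", decision, "' contains missing values (row ",
         which(is.na(y))[1L], ")", call. = FALSE)
  }
  out <- tibble::as_tibble(data[c(attrs, decision)])
  out[[decision]] <- as.character(y)
  structure(out, decision = decision,
            class = c("decision_table", class(out)))
}

#' @export
print.decision_table <- function(x, ...) {
  cat("# Decision table: ", nrow(x), " samples x ", ncol(x) - 1L,
      " attributes; decision = '", attr(x, "decision"), "' (",
      length(unique(x[[attr(x, "decision")]])), " classes)\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a decision table from CSV or ARFF
#'
#' CSV files need a header row; for ARFF the nominal class attribute becomes
#' the decision. All non-decision columns must parse as real numbers; a cell
#' that does not is reported with its row and column.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"arff"`. Guessed from the file extension by
#'   default.
#' @param decision Decision column, by name. Defaults to the last column.
#' @return A [decision_table()].
#' @export
read_decision_table <- function(path, format = c("auto", "csv", "arff"),
                                decision = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "arff") {
    raw <- foreign::read.arff(path)
    if (is.null(decision)) {
      nominal <- names(raw)[vapply(raw, is.factor, logical(1))]
      decision <- if (length(nominal)) nominal[length(nominal)] else names(raw)[ncol(raw)]
    }
    return(decision_table(raw, decision = decision))
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  decision <- decision %||% names(raw)[ncol(raw)]
  if (!decision %in% names(raw)) {
    stop("decision column '", decision, "' not present in ", path, call. = FALSE)
  }
  for (a in setdiff(names(raw), decision)) {
    v <- raw[[a]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value '", v[bad[1L]], "' in attribute column '", a,
             "', row ", bad[1L], " of ", path, call. = FALSE)
      }
      raw[[a]] <- num
    }
  }
  decision_table(raw, decision = decision)
}

#' Write a decision table to CSV
#'
#' @param x A decision table (or plain data frame).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_decision_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(x)), path)
  invisible(x)
}

#' Min-max normalize attribute columns to [0, 1]
#'
#' Each attribute column is rescaled as `(v - min) / (max - min)`; constant
#' columns map to all zeros so degenerate attributes flow through (and are
#' naturally never selected) instead of raising. The decision column is
#' untouched. The transform is idempotent.
#'
#' @param data A decision table or data frame.
#' @param decision Decision column name (taken from the table by default).
#' @return A [decision_table()] with all attributes in `[0, 1]`.
#' @export
normalize_minmax <- function(data, decision = NULL) {
  decision <- decision %||% attr(data, "decision") %||% names(data)[ncol(data)]
  out <- tibble::as_tibble(as.data.frame(data))
  for (a in setdiff(names(out), decision)) {
    v <- out[[a]]
    rng <- range(v)
    out[[a]] <- if (rng[1] == rng[2]) rep(0, length(v)) else (v - rng[1]) / (rng[2] - rng[1])
  }
  decision_table(out, decision = decision)
}

#' Simulate a synthetic decision table
#'
#' Generates Gaussian class clusters in `[0,1]^m` with optional redundant and
#' irrelevant attributes, emulating a (heavily down-scaled) gene-expression
#' matrix with known structure. Informative columns are drawn per class from
#' normals whose means are `class_separation` within-class standard
#' deviations apart, then min-max normalized. Redundant columns are noisy
#' copies (sd `noise_sd`) of informative columns; irrelevant columns are
#' uniform on `[0, 1]`. Class sizes are as equal as possible. The result is
#' a pure function of the arguments, including `seed`.
#'
#' @param n_samples Number of samples (rows).
#' @param n_informative Number of class-informative attributes (>= 1).
#' @param n_redundant Number of noisy copies of informative attributes.
#' @param n_irrelevant Number of uniform-noise attributes.
#' @param n_classes Number of decision classes (>= 2).
#' @param class_separation Distance between adjacent class means, in units of
#'   the within-class standard deviation. 0 means no class signal.
#' @param noise_sd Standard deviation (on the normalized `[0,1]` scale) of the
#'   noise added to redundant copies.
#' @param seed Integer seed; the generator leaves the global RNG untouched.
#' @return A [decision_table()] with attributes named `inf1..`, `red1..`,
#'   `irr1..` and decision column `class`.
#' @export
simulate_decision_table <- function(n_samples,
                                    n_informative,
                                    n_redundant = 0L,
                                    n_irrelevant = 0L,
                                    n_classes = 2L,
                                    class_separation = 3,
                                    noise_sd = 0.05,
                                    seed = 1L) {
  stopifnot(n_samples >= 1, n_informative >= 1, n_redundant >= 0,
            n_irrelevant >= 0, n_classes >= 2, class_separation >= 0,
            noise_sd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  cls <- rep_len(seq_len(n_classes), n_samples)  # as balanced as possible
  rescale01 <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) rep(0, length(v)) else (v - rng[1]) / (rng[2] - rng[1])
  }
  informative <- matrix(0, n_samples, n_informative)
  for (k in seq_len(n_informative)) {
    mu <- (cls - 1) * class_separation
    informative[, k] <- rescale01(stats::rnorm(n_samples, mean = mu, sd = 1))
  }
  cols <- list()
  for (k in seq_len(n_informative)) cols[[paste0("inf", k)]] <- informative[, k]
  if (n_redundant > 0) {
    src <- rep_len(seq_len(n_informative), n_redundant)
    for (k in seq_len(n_redundant)) {
      cols[[paste0("red", k)]] <-
        rescale01(informative[, src[k]] + stats::rnorm(n_samples, sd = noise_sd))
    }
  }
  if (n_irrelevant > 0) {
    for (k in seq_len(n_irrelevant)) {
      cols[[paste0("irr", k)]] <- stats::runif(n_samples)
    }
  }
  cols[["class"]] <- paste0("c", cls)
  decision_table(tibble::as_tibble(cols), decision = "class")
}

# Internal: resolved numeric context used by all measures.
# Returns X (matrix), y (character), attrs (names), classes (list of index
# vectors ordered by first appearance), n, m.
dt_context <- function(data, decision = NULL) {
  decision <- decision %||% attr(data, "decision") %||% names(data)[ncol(data)]
  stopifnot(decision %in% names(data))
  attrs <- setdiff(names(data), decision)
  X <- as.matrix(as.data.frame(data)[attrs])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("decision table contains missing attribute values", call. = FALSE)
  y <- as.character(data[[decision]])
  labs <- unique(y)
  classes <- lapply(labs, function(l) which(y == l))
  names(classes) <- labs
  list(X = X, y = y, attrs = attrs, classes = classes,
       n = nrow(X), m = ncol(X), decision = decision)
}

# Internal: resolve an attribute selection (names or indices) to indices.
resolve_attrs <- function(ctx, attributes) {
  if (is.null(attributes)) return(seq_len(ctx$m))
  if (is.character(attributes)) {
    idx <- match(attributes, ctx$attrs)
    if (anyNA(idx)) {
      stop("unknown attribute(s): ",
           paste(attributes[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(attributes)
  if (length(idx) && (min(idx) < 1L || max(idx) > ctx$m)) {
    stop("attribute index out of range 1..", ctx$m, call. = FALSE)
  }
  idx
}
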