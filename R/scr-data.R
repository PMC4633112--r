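#' Trap deployment array
#'
#' Builds the trap-array object used throughout the package: trap
#' identifiers, planar coordinates (already projected; km or abstract
#' units), and an optional trap-by-occasion binary operation mask.
#'
#' @param trap_id character or integer vector of unique trap identifiers.
#' @param x,y numeric planar coordinates, one per trap.
#' @param operation optional binary matrix (traps x occasions); 1 means the
#'   trap was operating during that occasion. Default: all-on (`NULL`).
#' @return An object of class `trap_array` with elements `trap_id`,
#'   `coords` (matrix with columns `x`, `y`) and `operation`.
#' @examples
#' tr <- trap_array(paste0("T", 1:4), x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
#' tr
#' @export
trap_array <- function(trap_id, x, y, operation = NULL) {
  trap_id <- as.character(trap_id)
  if (length(trap_id) == 0L) stop("no traps", call. = FALSE)
  if (anyDuplicated(trap_id))
    stop("duplicate trap id: ",
         paste(unique(trap_id[duplicated(trap_id)]), collapse = ", "),
         call. = FALSE)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(trap_id) || length(y) != length(trap_id))
    stop("coordinate vectors must match number of trap ids", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("trap coordinates must be finite", call. = FALSE)
  if (!is.null(operation)) {
    operation <- as.matrix(operation)
    if (nrow(operation) != length(trap_id))
      stop("operation mask rows must match trap count", call. = FALSE)
    if (!all(operation %in% c(0, 1)))
      stop("operation mask entries must be 0/1", call. = FALSE)
    storage.mode(operation) <- "integer"
  }
  structure(
    list(trap_id = trap_id,
         coords = cbind(x = x, y = y),
         operation = operation),
    class = "trap_array")
}

#' @export
print.trap_array <- function(x, ...) {
  cat("trap_array:", length(x$trap_id), "traps\n")
  cat("  x range:", paste(signif(range(x$coords[, "x"]), 5), collapse = " - "),
      " y range:", paste(signif(range(x$coords[, "y"]), 5), collapse = " - "),
      "\n")
  if (!is.null(x$operation))
    cat("  operation mask:", ncol(x$operation), "occasions\n")
  invisible(x)
}

n_traps <- function(traps) length(traps$trap_id)

#' Sampling-occasion calendar
#'
#' Partitions a study of `n_days` consecutive days into contiguous
#' sampling occasions. The standard schemes collapse a daily record into
#' weekly, monthly or quarterly intervals; a 91-day study yields 91, 13
#' (7-day weeks), 3 (30/30/31) and 1 occasions respectively, and a 90-day
#' study yields 90, 13 (12 weeks of 7 days plus one of 6), 3 (30/30/30)
#' and 1.
#'
#' @param n_days total study duration in days.
#' @param scheme one of `"daily"`, `"weekly"`, `"monthly"`, `"quarterly"`,
#'   or `"custom"` (then `lengths` is required).
#' @param lengths integer block lengths for `scheme = "custom"`; must sum
#'   to `n_days`.
#' @return An object of class `occasion_calendar` with `n_days`, `label`,
#'   and a `blocks` data.frame of `start` (1-based day index) and `length`.
#' @examples
#' occasion_calendar(91, "weekly")   # 13 occasions
#' occasion_calendar(90, "monthly")  # 3 occasions of 30 days
#' @export
occasion_calendar <- function(n_days,
                              scheme = c("daily", "weekly", "monthly",
                                         "quarterly", "custom"),
                              lengths = NULL) {
  scheme <- match.arg(scheme)
  n_days <- as.integer(n_days)
  if (n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  lens <- switch(scheme,
    daily = rep(1L, n_days),
    weekly = {
      full <- n_days %/% 7L; rem <- n_days %% 7L
      c(rep(7L, full), if (rem > 0L) rem)
    },
    monthly = {
      base <- n_days %/% 3L; rem <- n_days %% 3L
      # remainder days go to the last blocks (91 -> 30/30/31)
      base + c(rep(0L, 3L - rem), rep(1L, rem))
    },
    quarterly = n_days,
    custom = {
      if (is.null(lengths)) stop("custom scheme needs lengths", call. = FALSE)
      as.integer(lengths)
    })
  if (any(lens < 1L)) stop("occasion lengths must be >= 1 day", call. = FALSE)
  if (sum(lens) != n_days)
    stop("occasion blocks must cover the full study duration (",
         sum(lens), " != ", n_days, " days)", call. = FALSE)
  structure(
    list(n_days = n_days, label = scheme,
         blocks = data.frame(start = cumsum(c(1L, lens[-length(lens)])),
                             length = lens)),
    class = "occasion_calendar")
}

#' @export
print.occasion_calendar <- function(x, ...) {
  cat("occasion_calendar:", nrow(x$blocks), x$label, "occasions over",
      x$n_days, "days\n")
  invisible(x)
}

n_occasions <- function(calendar) nrow(calendar$blocks)

#' Capture history
#'
#' The binary individual x trap x occasion detection array together with
#' per-individual sex labels, the occasion calendar, and the trap array it
#' refers to. Multiple detections of the same individual at the same trap
#' within one occasion collapse to a single 1.
#'
#' @param y binary array, individuals x traps x occasions, with dimnames
#'   on the first margin giving individual ids (optional).
#' @param sex character vector per individual, `"F"`, `"M"` or `"U"`.
#' @param calendar an [occasion_calendar()].
#' @param traps a [trap_array()].
#' @return An object of class `capture_history`.
#' @export
capture_history <- function(y, sex, calendar, traps) {
  y <- as.array(y)
  if (length(dim(y)) != 3L)
    stop("y must be a 3-d individual x trap x occasion array", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y entries must be 0/1", call. = FALSE)
  storage.mode(y) <- "integer"
  if (dim(y)[2] != n_traps(traps))
    stop("y trap dimension does not match trap array", call. = FALSE)
  if (dim(y)[3] != n_occasions(calendar))
    stop("y occasion dimension does not match calendar", call. = FALSE)
  if (length(sex) != dim(y)[1])
    stop("sex labels must match number of individuals", call. = FALSE)
  sex <- toupper(as.character(sex))
  if (!all(sex %in% c("F", "M", "U")))
    stop("sex labels must be F, M or U", call. = FALSE)
  names(sex) <- dimnames(y)[[1]]
  if (dim(y)[1] > 0 && any(apply(y, 1, sum) == 0))
    stop("every listed individual must have at least one detection",
         call. = FALSE)
  structure(list(y = y, sex = sex, calendar = calendar, traps = traps),
            class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  cat("capture_history:", dim(x$y)[1], "individuals x", dim(x$y)[2],
      "traps x", dim(x$y)[3], "occasions (", x$calendar$label, ")\n")
  cat("  detections:", sum(x$y), "; sex:",
      sum(x$sex == "F"), "F /", sum(x$sex == "M"), "M /",
      sum(x$sex == "U"), "U\n")
  invisible(x)
}

n_individuals <- function(history) dim(history$y)[1]

#' Read a trap deployment table
#'
#' Reads a delimited text file with header `trap_id,x,y` and optional
#' per-occasion operation columns `op_1 .. op_K`.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return A [trap_array()].
#' @export
read_traps <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no traps", call. = FALSE)
  need <- c("trap_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("trap file needs columns trap_id, x, y", call. = FALSE)
  xy <- lapply(c("x", "y"), function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric ", col, " coordinate in row ", bad[1], call. = FALSE)
    v
  })
  opcols <- grep("^op_[0-9]+$", names(df), value = TRUE)
  op <- NULL
  if (length(opcols)) {
    opcols <- opcols[order(as.integer(sub("^op_", "", opcols)))]
    op <- sapply(opcols, function(col) as.integer(df[[col]]))
    op <- matrix(op, nrow = nrow(df))
  }
  trap_array(df$trap_id, xy[[1]], xy[[2]], operation = op)
}

#' Write a trap deployment table
#'
#' @param traps a [trap_array()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traps <- function(traps, path) {
  df <- data.frame(trap_id = traps$trap_id,
                   x = traps$coords[, "x"], y = traps$coords[, "y"])
  if (!is.null(traps$operation)) {
    op <- as.data.frame(traps$operation)
    names(op) <- paste0("op_", seq_len(ncol(op)))
    df <- cbind(df, op)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format capture table
#'
#' Reads delimited records `individual,trap_id,day,sex` (sex in F/M/U)
#' and builds the binary capture history at the resolution of `calendar`.
#' Repeated records of the same individual at the same trap within one
#' occasion collapse to a single detection.
#'
#' @param path file path.
#' @param traps a [trap_array()]; trap ids in the file must resolve here.
#' @param calendar an [occasion_calendar()] covering the study days.
#' @param sep field separator.
#' @return A [capture_history()].
#' @export
read_captures <- function(path, traps, calendar, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("individual", "trap_id", "day", "sex")
  if (!all(need %in% names(df)))
    stop("capture file needs columns individual, trap_id, day, sex",
         call. = FALSE)
  captures_from_records(df, traps, calendar)
}

#' Build a capture history from in-memory long-format records
#'
#' Converter hook for other table layouts: reshape to a data.frame with
#' columns `individual`, `trap_id`, `day` (1-based day index), `sex` and
#' pass it here.
#'
#' @param records data.frame of capture records.
#' @inheritParams read_captures
#' @return A [capture_history()].
#' @export
captures_from_records <- function(records, traps, calendar) {
  if (nrow(records) == 0L)
    return(capture_history(
      array(0L, c(0L, n_traps(traps), n_occasions(calendar))),
      character(0), calendar, traps))
  jt <- match(as.character(records$trap_id), traps$trap_id)
  if (anyNA(jt))
    stop("unknown trap id: ",
         paste(unique(records$trap_id[is.na(jt)]), collapse = ", "),
         call. = FALSE)
  day <- as.integer(records$day)
  if (any(is.na(day)) || any(day < 1L) || any(day > calendar$n_days))
    stop("capture day outside the calendar (1..", calendar$n_days, ")",
         call. = FALSE)
  occ <- day_to_occasion(calendar)[day]
  ids <- as.character(records$individual)
  uid <- unique(ids)
  it <- match(ids, uid)
  sex_by_id <- vapply(uid, function(id) {
    sx <- setdiff(unique(toupper(records$sex[ids == id])), "U")
    if (length(sx) > 1L)
      stop("conflicting sex labels for individual ", id, call. = FALSE)
    if (length(sx) == 0L) "U" else sx
  }, character(1))
  y <- array(0L, c(length(uid), n_traps(traps), n_occasions(calendar)),
             dimnames = list(uid, traps$trap_id, NULL))
  y[cbind(it, jt, occ)] <- 1L
  capture_history(y, sex_by_id, calendar, traps)
}

#' Write a capture history as a long-format table
#'
#' Writes one record per 1-entry of the binary array, with `day` the first
#' day of the corresponding occasion block, so that reading the file back
#' against the same calendar reproduces the identical array.
#'
#' @param history a [capture_history()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(history, path) {
  idx <- which(history$y == 1L, arr.ind = TRUE)
  ids <- dimnames(history$y)[[1]]
  if (is.null(ids)) ids <- paste0("ind", seq_len(n_individuals(history)))
  df <- data.frame(
    individual = ids[idx[, 1]],
    trap_id = history$traps$trap_id[idx[, 2]],
    day = history$calendar$blocks$start[idx[, 3]],
    sex = history$sex[idx[, 1]])
  df <- df[order(df$individual, df$day, df$trap_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

day_to_occasion <- function(calendar) {
  rep(seq_len(n_occasions(calendar)), calendar$blocks$length)
}

#' Collapse a capture history to coarser sampling occasions
#'
#' Collapses occasions by logical OR within each block of the target
#' scheme: a collapsed individual-trap cell is 1 if the individual was
#' detected at that trap on any day of the block. The individual set is
#' unchanged and the total count of detections is non-increasing. Any
#' trap operation mask collapses the same way (a trap operated during a
#' collapsed occasion if it operated on any day of it).
#'
#' @param history a [capture_history()].
#' @param scheme an [occasion_calendar()] whose blocks partition the same
#'   study days, or a scheme name passed to [occasion_calendar()].
#' @return A [capture_history()] at the collapsed resolution.
#' @examples
#' \dontrun{
#' weekly <- aggregate_occasions(daily_history, "weekly")
#' }
#' @export
aggregate_occasions <- function(history, scheme) {
  if (is.character(scheme))
    scheme <- occasion_calendar(history$calendar$n_days, scheme)
  if (scheme$n_days != history$calendar$n_days)
    stop("scheme does not cover the study duration", call. = FALSE)
  src <- history$calendar
  if (identical(src$blocks, scheme$blocks)) {
    history$calendar <- scheme
    return(history)
  }
  # each source occasion must fall entirely inside one target block
  src_block <- day_to_occasion(scheme)
  src_start <- src$blocks$start
  src_end <- src_start + src$blocks$length - 1L
  tgt <- src_block[src_start]
  if (any(src_block[src_end] != tgt))
    stop("scheme blocks must align with source occasion boundaries",
         call. = FALSE)
  nI <- n_individuals(history); nJ <- n_traps(history$traps)
  nK <- n_occasions(scheme)
  y2 <- array(0L, c(nI, nJ, nK), dimnames = dimnames(history$y)[c(1, 2)])
  for (k in seq_len(nK)) {
    sel <- which(tgt == k)
    yk <- history$y[, , sel, drop = FALSE]
    y2[, , k] <- (apply(yk, c(1, 2), sum) > 0L) * 1L
  }
  traps <- history$traps
  if (!is.null(traps$operation)) {
    op2 <- sapply(seq_len(nK), function(k)
      (rowSums(traps$operation[, which(tgt == k), drop = FALSE]) > 0L) * 1L)
    traps$operation <- matrix(op2, nrow = nJ)
  }
  capture_history(y2, history$sex, scheme, traps)
}

#' Discretize a buffered statespace around a trap array
#'
#' Expands the trap bounding box by `buffer` on every side (rectangular
#' convention) and lays a regular grid of pixel centers with the given
#' spacing; each pixel represents `spacing^2` area units. Optionally masks
#' the rectangle to the union of discs of radius `buffer` around the traps.
#'
#' @param traps a [trap_array()].
#' @param buffer buffer distance (>= 0), same units as the coordinates.
#' @param spacing pixel side length (> 0).
#' @param mask `"rectangle"` (default) or `"disc"` for the union-of-discs
#'   mask.
#' @return An object of class `statespace` with `pixel_centers` (matrix),
#'   `pixel_area`, `total_area`, `spacing`, and `extent`
#'   (xmin/xmax/ymin/ymax of the buffered rectangle).
#' @examples
#' tr <- trap_array(1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
#' build_statespace(tr, buffer = 2, spacing = 0.5)
#' @export
build_statespace <- function(traps, buffer, spacing,
                             mask = c("rectangle", "disc")) {
  mask <- match.arg(mask)
  if (buffer < 0) stop("buffer must be >= 0", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  xr <- range(traps$coords[, "x"]); yr <- range(traps$coords[, "y"])
  ext <- c(xmin = xr[1] - buffer, xmax = xr[2] + buffer,
           ymin = yr[1] - buffer, ymax = yr[2] + buffer)
  if (ext["xmax"] - ext["xmin"] < 2 * spacing ||
      ext["ymax"] - ext["ymin"] < 2 * spacing)
    stop("degenerate statespace: fewer than 4 pixels; reduce spacing",
         call. = FALSE)
  gx <- seq(ext["xmin"] + spacing / 2, ext["xmax"] - spacing / 2 + 1e-9,
            by = spacing)
  gy <- seq(ext["ymin"] + spacing / 2, ext["ymax"] - spacing / 2 + 1e-9,
            by = spacing)
  centers <- as.matrix(expand.grid(x = gx, y = gy))
  if (mask == "disc") {
    d2 <- pairwise_dist2(centers, traps$coords)
    keep <- apply(d2, 1, min) <= buffer^2 + 1e-9
    centers <- centers[keep, , drop = FALSE]
  }
  if (nrow(centers) < 4L)
    stop("degenerate statespace: fewer than 4 pixels; reduce spacing",
         call. = FALSE)
  structure(
    list(pixel_centers = centers,
         pixel_area = spacing^2,
         total_area = nrow(centers) * spacing^2,
         spacing = spacing,
         extent = ext),
    class = "statespace")
}

#' @export
print.statespace <- function(x, ...) {
  cat("statespace:", nrow(x$pixel_centers), "pixels of",
      signif(x$pixel_area, 5), "area units^2; total area",
      signif(x$total_area, 6), "\n")
  invisible(x)
}

n_pixels <- function(space) nrow(space$pixel_centers)

#' Export a statespace pixel grid as CSV
#'
#' @param space a [build_statespace()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_statespace <- function(space, path) {
  df <- data.frame(pixel_id = seq_len(n_pixels(space)),
                   x = space$pixel_centers[, "x"],
                   y = space$pixel_centers[, "y"],
                   area = space$pixel_area)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# squared distances between rows of two coordinate matrices
pairwise_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}
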