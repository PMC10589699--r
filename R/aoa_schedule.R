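#' Construct an acquisition table
#'
#' Monthwise cumulative acquisition probabilities: `probs[i, m]` is the
#' probability that concept i is produced by month m (the MB-CDI item
#' trajectory layout). Probabilities must be cumulative over months;
#' violations of monotonicity are repaired by a running maximum, with a
#' warning.
#'
#' @param probs numeric matrix, one row per concept, one column per month,
#'   entries in \[0, 1\].
#' @param concepts character labels, one per row.
#' @param months integer month labels, one per column.
#' @return An object of class `acquisition_table`.
#' @export
acquisition_table <- function(probs, concepts, months) {
  probs <- as.matrix(probs)
  concepts <- as.character(concepts)
  months <- as.integer(months)
  stopifnot(nrow(probs) == length(concepts), ncol(probs) == length(months))
  if (anyDuplicated(concepts)) stop("duplicate concept labels in acquisition table")
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("acquisition probabilities must be finite and in [0, 1]")
  }
  if (is.unsorted(months, strictly = TRUE)) stop("months must be strictly increasing")
  if (ncol(probs) > 1) {
    mono <- t(apply(probs, 1, cummax))
    if (any(mono != probs)) {
      warning("non-monotone acquisition probabilities clipped to cumulative maxima")
      probs <- mono
    }
  }
  dimnames(probs) <- list(concepts, as.character(months))
  structure(list(concepts = concepts, months = months, probs = probs),
            class = "acquisition_table")
}

#' @export
print.acquisition_table <- function(x, ...) {
  cat(sprintf("<acquisition_table: %d concepts, months %d-%d>\n",
              length(x$concepts), min(x$months), max(x$months)))
  invisible(x)
}

#' Read an MB-CDI style item-trajectory CSV
#'
#' Expects a header row with an item-label column plus one column per month
#' (month columns named by the bare month number, e.g. `16`, or `X16` as
#' written by [utils::read.csv()] round trips).
#'
#' @param path CSV file path.
#' @param month_range two integers; the table is restricted to months in this
#'   closed range (default 16 to 24, where MB-CDI coverage of the true
#'   vocabulary is near-complete).
#' @param item_col name of the item-label column (default `"item"`).
#' @param pair optional [intersect_systems()] result; if supplied, rows are
#'   restricted to its shared vocabulary.
#' @param lowercase lowercase item labels before matching.
#' @param alias_map optional named character vector mapping raw item labels
#'   (e.g. multiword MB-CDI items) to embedding tokens. Multiword items with
#'   no alias are dropped with a warning.
#' @return An [acquisition_table()].
#' @export
load_acquisition_table <- function(path, month_range = c(16L, 24L),
                                   item_col = "item", pair = NULL,
                                   lowercase = TRUE, alias_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!item_col %in% names(df)) stop("item column '", item_col, "' not found")
  items <- as.character(df[[item_col]])
  if (lowercase) items <- tolower(items)
  if (!is.null(alias_map)) {
    hit <- items %in% names(alias_map)
    items[hit] <- unname(alias_map[items[hit]])
  }
  multi <- grepl("[[:space:]]", items)
  if (any(multi)) {
    warning("dropping ", sum(multi), " multiword item(s) without alias: ",
            paste(utils::head(items[multi], 5), collapse = ", "))
    df <- df[!multi, , drop = FALSE]
    items <- items[!multi]
  }
  month_cols <- setdiff(names(df), item_col)
  month_num <- suppressWarnings(as.integer(sub("^X", "", month_cols)))
  keep <- !is.na(month_num) & month_num >= month_range[1] & month_num <= month_range[2]
  wanted <- seq(month_range[1], month_range[2])
  if (!all(wanted %in% month_num[keep])) {
    stop("missing month columns in range: ",
         paste(setdiff(wanted, month_num[keep]), collapse = ", "))
  }
  ord <- order(month_num[keep])
  probs <- as.matrix(df[, month_cols[keep], drop = FALSE])[, ord, drop = FALSE]
  storage.mode(probs) <- "double"
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("acquisition probabilities outside [0, 1] (or missing)")
  }
  if (!is.null(pair)) {
    inpair <- items %in% pair$shared_concepts
    probs <- probs[inpair, , drop = FALSE]
    items <- items[inpair]
    if (length(items) == 0) stop("no table rows match the system pair vocabulary")
  }
  acquisition_table(probs, items, sort(month_num[keep]))
}

#' Write an acquisition table as an item-trajectory CSV
#'
#' Emits the dialect read by [load_acquisition_table()].
#'
#' @param table an [acquisition_table()].
#' @param path output path.
#' @param item_col item-label column name.
#' @export
write_acquisition_table <- function(table, path, item_col = "item") {
  stopifnot(inherits(table, "acquisition_table"))
  df <- data.frame(table$concepts, table$probs, check.names = FALSE)
  names(df) <- c(item_col, as.character(table$months))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a monthly schedule
#'
#' @param months ordered integer months.
#' @param n_m concepts acquired in each month (nonnegative integers).
#' @return An object of class `month_schedule` with fields `months`, `n_m`
#'   and cumulative `N_m`.
#' @export
month_schedule <- function(months, n_m) {
  months <- as.integer(months)
  n_m <- as.integer(n_m)
  stopifnot(length(months) == length(n_m))
  if (any(n_m < 0)) stop("negative monthly count")
  structure(list(months = months, n_m = n_m, N_m = cumsum(n_m)),
            class = "month_schedule")
}

#' Monthly acquisition counts from an acquisition table
#'
#' The cumulative count through month m is the rounded sum of cumulative
#' acquisition probabilities, N_m = round(sum_i p_im) (half away from zero);
#' per-month counts are obtained by differencing, with the first month's
#' count equal to its cumulative count.
#'
#' @param table an [acquisition_table()].
#' @return A [month_schedule()].
#' @export
monthly_counts <- function(table) {
  stopifnot(inherits(table, "acquisition_table"))
  N_m <- as.integer(round_half_away(colSums(table$probs)))
  n_m <- diff(c(0L, N_m))
  if (any(n_m < 0)) stop("non-monotone acquisition table: negative monthly count after rounding")
  month_schedule(table$months, n_m)
}

#' Published WordBank monthly acquisition counts (English, American)
#'
#' The per-month numbers of concepts acquired between 16 and 24 months of
#' age, computed from WordBank MB-CDI production-trajectory proportions for
#' the 138-word concept set used throughout this package's reference
#' analyses (cumulative probabilities summed per month and rounded to the
#' nearest whole concept).
#'
#' @return A [month_schedule()] with months 16:24, cumulative counts
#'   (17, 21, 36, 45, 49, 55, 68, 77, 83) and per-month counts derived by
#'   differencing.
#' @export
cdi_month_schedule <- function() {
  N_m <- c(17L, 21L, 36L, 45L, 49L, 55L, 68L, 77L, 83L)
  month_schedule(16:24, diff(c(0L, N_m)))
}

#' Sampling distribution over unacquired AoA concepts
#'
#' Normalizes the acquisition probabilities at `month` over the concepts not
#' yet in the knowledge state, so they sum to 1. If every remaining concept
#' has zero probability, falls back to a uniform distribution with a warning.
#'
#' @param table an [acquisition_table()].
#' @param month integer month (must be one of `table$months`).
#' @param known character vector of already-acquired concept labels.
#' @return Named probability vector over the unacquired table concepts.
#' @export
acquisition_distribution <- function(table, month, known = character(0)) {
  stopifnot(inherits(table, "acquisition_table"))
  col <- match(month, table$months)
  if (is.na(col)) stop("month ", month, " not in table")
  remaining <- setdiff(table$concepts, known)
  if (length(remaining) == 0) stop("no unacquired concepts remain")
  p <- table$probs[remaining, col]
  total <- sum(p)
  if (total <= 0) {
    warning("all remaining acquisition probabilities are zero; using uniform")
    p <- rep(1 / length(remaining), length(remaining))
  } else {
    p <- p / total
  }
  names(p) <- remaining
  p
}

#' Bootstrapped acquisition-probability distributions
#'
#' Generates B bootstrap tables: each is built by simulating
#' `seqs_per_boot` acquisition trajectories under the AoA sampling rules
#' (one concept at a time from [acquisition_distribution()], following
#' `schedule`) and recording, per concept and month, the proportion of
#' trajectories in which the concept was acquired by that month. A 70/30
#' train/validation split over the B tables is recorded.
#'
#' @param table an [acquisition_table()].
#' @param B number of bootstrap tables (>= 2).
#' @param seqs_per_boot trajectories per table.
#' @param schedule a [month_schedule()]; defaults to [monthly_counts()] of
#'   the table.
#' @param seed integer seed.
#' @param train_frac fraction of tables assigned to the training split.
#' @return An object of class `bootstrap_set`: list with `dists` (a list of
#'   B concept-by-month probability matrices), `train_idx`, `validation_idx`,
#'   `months`, `concepts`.
#' @export
bootstrap_distributions <- function(table, B = 1000, seqs_per_boot = 300,
                                    schedule = NULL, seed = 1,
                                    train_frac = 0.7) {
  stopifnot(inherits(table, "acquisition_table"), B >= 2, seqs_per_boot >= 1)
  schedule <- schedule %||% monthly_counts(table)
  if (max(schedule$N_m) > length(table$concepts)) {
    stop("schedule demands more concepts than the table contains")
  }
  set.seed(as.integer(seed))
  n <- length(table$concepts)
  M <- length(schedule$months)
  dists <- vector("list", B)
  for (b in seq_len(B)) {
    counts <- matrix(0, n, M, dimnames = list(table$concepts, as.character(schedule$months)))
    for (s in seq_len(seqs_per_boot)) {
      known <- character(0)
      for (mi in seq_len(M)) {
        for (slot in seq_len(schedule$n_m[mi])) {
          p <- suppressWarnings(
            acquisition_distribution(table, schedule$months[mi], known))
          pick <- sample(names(p), 1, prob = p)
          known <- c(known, pick)
        }
        counts[known, mi] <- counts[known, mi] + 1
      }
    }
    dists[[b]] <- counts / seqs_per_boot
  }
  n_train <- max(1L, floor(train_frac * B))
  idx <- sample.int(B)
  structure(list(dists = dists,
                 train_idx = sort(idx[seq_len(n_train)]),
                 validation_idx = sort(idx[-seq_len(n_train)]),
                 months = schedule$months, concepts = table$concepts),
            class = "bootstrap_set")
}
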