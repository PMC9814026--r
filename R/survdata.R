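#' Construct a survival dataset
#'
#' Builds the basic data container used throughout the package: one row per
#' observation, with an observed time \code{y = min(t, c)}, an event
#' indicator \code{d} (1 = event, 0 = right-censored) and a group label.
#' Groups index correlated observations (e.g. the two kidneys of one
#' patient); group labels may be arbitrary and are mapped to dense indices
#' \code{1..n} in order of first appearance, which is the canonical order
#' used for the frailty block of the latent field.
#'
#' @param time positive numeric vector of observed times.
#' @param event 0/1 vector of event indicators.
#' @param group vector of group labels (any type); defaults to one group
#'   per observation (independent data).
#' @param covariates optional data frame of covariate columns, one row per
#'   observation.
#' @param coords optional two-column matrix of spatial coordinates.
#' @return An object of class \code{survival_dataset} with components
#'   \code{time}, \code{event}, \code{group} (integer codes),
#'   \code{group_levels}, \code{n_groups}, \code{group_sizes}, \code{total},
#'   \code{covariates}, \code{coords}.
#' @export
survival_dataset <- function(time, event, group = seq_along(time),
                             covariates = NULL, coords = NULL) {
  time <- as.numeric(time)
  N <- length(time)
  if (N == 0L) stop("dataset is empty: no observations")
  if (length(event) != N) stop("time and event lengths differ")
  bad_t <- which(!is.finite(time) | time <= 0)
  if (length(bad_t)) {
    stop("non-positive or non-finite time at row ", bad_t[1L])
  }
  event <- as.numeric(event)
  bad_d <- which(!(event %in% c(0, 1)))
  if (length(bad_d)) {
    stop("event indicator not in {0,1} at row ", bad_d[1L])
  }
  if (length(group) != N) stop("group length differs from time")
  lev <- unique(as.character(group))
  gidx <- match(as.character(group), lev)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != N) stop("covariates must have one row per observation")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != N || ncol(coords) != 2L) {
      stop("coords must be an N x 2 matrix")
    }
  }
  structure(
    list(time = time, event = as.integer(event), group = gidx,
         group_levels = lev, n_groups = length(lev),
         group_sizes = as.integer(tabulate(gidx, nbins = length(lev))),
         total = N, covariates = covariates, coords = coords),
    class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("Survival dataset: N =", x$total, "observations in n =", x$n_groups,
      "groups;", sum(x$event), "events,",
      sum(x$event == 0), "right-censored\n")
  if (!is.null(x$covariates)) {
    cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  if (!is.null(x$coords)) cat("Spatial coordinates present\n")
  invisible(x)
}

#' Read a survival dataset from CSV
#'
#' Reads a comma-separated file with a header row.  Default column names
#' are \code{group}, \code{time}, \code{status}; remaining columns are
#' kept as covariates, and columns \code{coord_x}/\code{coord_y} (when
#' present) become spatial coordinates.  Names can be remapped through
#' \code{schema}.
#'
#' @param path path to a CSV file.
#' @param schema named list overriding default column names, e.g.
#'   \code{list(time = "y", event = "d", group = "id")}.  Recognised keys:
#'   \code{time}, \code{event}, \code{group}, \code{coord_x},
#'   \code{coord_y}.
#' @return A [survival_dataset()].
#' @export
read_survival_data <- function(path, schema = list()) {
  if (!file.exists(path)) stop("data file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("dataset is empty: ", path)
  nm <- list(time = "time", event = "status", group = "group",
             coord_x = "coord_x", coord_y = "coord_y")
  nm[names(schema)] <- schema
  for (key in c("time", "event", "group")) {
    if (!nm[[key]] %in% names(df)) {
      stop("missing required column '", nm[[key]], "' (schema key '", key, "')")
    }
  }
  has_coords <- nm$coord_x %in% names(df) && nm$coord_y %in% names(df)
  used <- unlist(nm[c("time", "event", "group")])
  if (has_coords) used <- c(used, nm$coord_x, nm$coord_y)
  cov_cols <- setdiff(names(df), used)
  survival_dataset(
    time = df[[nm$time]], event = df[[nm$event]], group = df[[nm$group]],
    covariates = if (length(cov_cols)) df[cov_cols] else NULL,
    coords = if (has_coords) cbind(df[[nm$coord_x]], df[[nm$coord_y]]) else NULL)
}

#' Risk-set index with Breslow tie handling
#'
#' Sorts the observations by time and records, for each event, the start of
#' the contiguous span of the sorted array that forms its risk set
#' \eqn{R_{ij} = \{(k,l): y_{kl} \ge y_{ij}\}}.  Tied events (and censored
#' observations tied with them) share the identical full risk set, the
#' Breslow convention.
#'
#' @param data a [survival_dataset()].
#' @return An object of class \code{risk_set_index} with components
#'   \code{order} (permutation into increasing time), \code{event_sorted}
#'   (0/1 in sorted order), \code{risk_start} (for every sorted position,
#'   the first sorted position of its tie group, i.e. the start of the risk
#'   set of an event at that time), \code{event_positions} (sorted
#'   positions of events), \code{risk_sizes} (risk-set size per event).
#' @export
build_risk_sets <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  if (sum(data$event) == 0L) {
    stop("no events in dataset: partial likelihood is constant")
  }
  N <- data$total
  ord <- order(data$time)            # increasing time
  t_s <- data$time[ord]
  d_s <- data$event[ord]
  # first index of each tie group: risk set of an event at position i is
  # positions risk_start[i]..N
  new_grp <- c(TRUE, t_s[-1L] > t_s[-N])
  risk_start <- cummax(ifelse(new_grp, seq_len(N), 0L))
  ev_pos <- which(d_s == 1L)
  structure(
    list(order = ord, time_sorted = t_s, event_sorted = d_s,
         risk_start = as.integer(risk_start),
         event_positions = ev_pos,
         risk_sizes = N - risk_start[ev_pos] + 1L,
         n = N),
    class = "risk_set_index")
}

#' Risk-set membership for one event (exhaustive definition)
#'
#' Returns the original-order indices of the records in the risk set of the
#' event at sorted position \code{pos}.  Intended for inspection and
#' testing; the likelihood code uses the cumulative structure directly.
#'
#' @param risk a [build_risk_sets()] index.
#' @param pos a sorted position (typically one of \code{event_positions}).
#' @return Integer vector of original row indices.
#' @export
risk_set_members <- function(risk, pos) {
  stopifnot(inherits(risk, "risk_set_index"))
  risk$order[risk$risk_start[pos]:risk$n]
}
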