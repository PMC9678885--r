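#' Marker roles used by the default annotation rules
#'
#' Surface markers drive population calls, cycle and death markers drive
#' cell-cycle phase / viability calls.
#' @keywords internal
marker_roles <- function() {
  list(
    surface = c("CD45", "CD45RA", "CD34", "CD19"),
    cycle = c("pRb", "IdU", "CycB1", "pHisH3"),
    death = c("cisplatin", "cCaspase3")
  )
}

#' Arcsinh transform and quantile scaling of an event matrix
#'
#' Standard mass-cytometry preprocessing: raw ion counts are transformed with
#' `asinh(x / cofactor)` and each marker is then linearly rescaled so that
#' its 1st percentile maps to 0 and its 99th percentile to 1, clipping
#' outside [0, 1]. Negative ion counts are clipped to 0 first (their count is
#' reported).
#'
#' @param raw numeric events x markers matrix.
#' @param cofactor arcsinh cofactor (> 0; default 5).
#' @param probs two quantiles anchoring the scaling (default 1st and 99th
#'   percentile).
#' @param rescale if `FALSE`, return the arcsinh-transformed values without
#'   quantile scaling.
#' @return transformed matrix with the same dimnames.
#' @export
arcsinh_scale <- function(raw, cofactor = 5, probs = c(0.01, 0.99),
                          rescale = TRUE) {
  if (cofactor <= 0) stop("cofactor must be > 0")
  raw <- as.matrix(raw)
  neg <- sum(raw < 0)
  if (neg > 0) {
    message(neg, " negative ion count(s) clipped to 0")
    raw[raw < 0] <- 0
  }
  tr <- asinh(raw / cofactor)
  if (!rescale) return(tr)
  for (j in seq_len(ncol(tr))) {
    q <- quantile(tr[, j], probs = probs, names = FALSE)
    if (q[2] > q[1]) {
      tr[, j] <- (tr[, j] - q[1]) / (q[2] - q[1])
    } else {
      tr[, j] <- 0
    }
  }
  tr[tr < 0] <- 0
  tr[tr > 1] <- 1
  tr
}

#' Train a batch self-organizing map
#'
#' Batch SOM on a rectangular grid: each epoch assigns every event to its
#' nearest codebook vector (Euclidean) and replaces each codebook with the
#' neighborhood-weighted mean of all events, with a Gaussian neighborhood
#' whose width decays linearly from half the grid radius to (effectively)
#' zero, so the final epochs perform nearly hard within-node averaging and
#' the map converges to local means. Batch updates make the result
#' independent of event order; codebooks are initialised from a seeded
#' random sample of events, so the fit is fully reproducible given the seed.
#' Nodes that receive no neighborhood mass in an epoch keep their previous
#' codebook.
#'
#' @param data numeric events x markers matrix (transformed scale).
#' @param grid integer vector `c(g1, g2)` (default 10 x 10).
#' @param epochs training epochs (default 10).
#' @param seed integer seed (mandatory).
#' @return list of class `som_model`: `codebook` (nodes x markers), `grid`,
#'   `epochs`, `seed`, `quantization_error` (per-epoch trajectory).
#' @export
train_som <- function(data, grid = c(10, 10), epochs = 10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  data <- as.matrix(data)
  n_nodes <- prod(grid)
  if (nrow(data) < n_nodes) {
    stop("fewer events (", nrow(data), ") than nodes (", n_nodes,
         "); use a smaller grid")
  }
  set.seed(seed)
  codebook <- data[sample.int(nrow(data), n_nodes), , drop = FALSE]
  gx <- rep(seq_len(grid[1]), times = grid[2])
  gy <- rep(seq_len(grid[2]), each = grid[1])
  grid_d2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2
  radius <- max(grid - 1) / 2
  sigmas <- if (epochs == 1) 0.05 else
    seq(radius / 2, 0.05, length.out = epochs)
  sigmas <- pmax(sigmas, 0.05)
  x2 <- rowSums(data^2)
  qe <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    d2 <- outer(x2, rowSums(codebook^2), "+") - 2 * data %*% t(codebook)
    bmu <- max.col(-d2, ties.method = "first")
    qe[ep] <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(data)), bmu)], 0)))
    h <- exp(-grid_d2 / (2 * sigmas[ep]^2))   # nodes x nodes
    # events-per-node indicator aggregated to node sums
    node_sum <- rowsum(data, group = bmu, reorder = FALSE)
    node_n <- tabulate(bmu, nbins = n_nodes)
    full_sum <- matrix(0, n_nodes, ncol(data))
    full_sum[as.integer(rownames(node_sum)), ] <- node_sum
    num <- h %*% full_sum
    den <- as.vector(h %*% node_n)
    upd <- den > 1e-12
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  colnames(codebook) <- colnames(data)
  structure(list(codebook = codebook, grid = grid, epochs = epochs,
                 seed = seed, quantization_error = qe),
            class = "som_model")
}

#' Map events to their nearest SOM node
#'
#' @param model a [train_som()] fit.
#' @param data events x markers matrix on the same scale as the training data.
#' @return integer vector of node indices.
#' @export
som_map <- function(model, data) {
  data <- as.matrix(data)
  d2 <- outer(rowSums(data^2), rowSums(model$codebook^2), "+") -
    2 * data %*% t(model$codebook)
  max.col(-d2, ties.method = "first")
}

#' Per-marker high/low thresholds from a two-component Gaussian mixture
#'
#' For each marker, fits a one-dimensional two-component Gaussian mixture to
#' all events and takes the midpoint of the two component means as the
#' "high" threshold. When the fitted means are closer than `min_sep`
#' (degenerate, unimodal marker) the marker median is used instead.
#'
#' @param data events x markers matrix (transformed scale).
#' @param markers columns to threshold (default all).
#' @param min_sep minimum component-mean separation (default 0.1 scaled units).
#' @param seed integer seed for the mixture fit.
#' @return named numeric vector of thresholds.
#' @export
marker_thresholds <- function(data, markers = colnames(data), min_sep = 0.1,
                              seed = 1) {
  set.seed(seed)
  vapply(markers, function(m) {
    x <- data[, m]
    # equal-variance components: robust against splitting a skewed
    # dominant mode instead of separating the low and high levels
    fit <- tryCatch(
      Mclust(x, G = 2, modelNames = "E", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || abs(diff(fit$parameters$mean)) < min_sep) {
      median(x)
    } else {
      mean(fit$parameters$mean)
    }
  }, numeric(1))
}

#' Default annotation rules for cell-cycle phase and viability
#'
#' Ordered first-match rules over metacluster medians: dead (cisplatin
#' high), apoptotic (cleaved caspase-3 high), M (pHisH3 high), S (IdU high),
#' G2 (CycB1 high), G1 (pRb high), else G0.
#'
#' @return list of rules; each rule has `label` and character vectors
#'   `high` / `low` / `mid` of marker conditions.
#' @export
default_phase_rules <- function() {
  list(
    list(label = "dead", high = "cisplatin"),
    list(label = "apoptotic", high = "cCaspase3"),
    list(label = "M", high = "pHisH3"),
    list(label = "S", high = "IdU"),
    list(label = "G2", high = "CycB1"),
    list(label = "G1", high = "pRb"),
    list(label = "G0")
  )
}

#' Default annotation rules for cell populations
#'
#' Ordered first-match rules using surface markers: CD19-low B-cell
#' precursors (intermediate CD19 and CD34), HSPC (CD34+CD19-), preB
#' (CD19+CD34-), CD45RA (CD45RA+CD34-CD19-), remainder CD45. All events are
#' assumed to be pre-gated viable CD45+ single cells (the usual upstream
#' selection), so CD45 itself carries no contrast and only names the
#' catch-all; `mid` means the metacluster median lies within the `mid_band`
#' of the threshold, capturing the "lo" expression level.
#'
#' @return list of rules as in [default_phase_rules()].
#' @export
default_population_rules <- function() {
  list(
    list(label = "CD19low", mid = "CD19"),
    list(label = "HSPC", high = "CD34", low = "CD19"),
    list(label = "preB", high = "CD19", low = "CD34"),
    list(label = "CD45RA", high = "CD45RA", low = c("CD34", "CD19")),
    list(label = "CD45")
  )
}

# high: above threshold; low: at or below; mid: within mid_band of it.
# Rules are applied in order, so earlier rules (e.g. the intermediate-level
# CD19low call) take precedence over later plain high/low calls.
rule_matches <- function(med, rule, thresholds, mid_band) {
  ok <- TRUE
  for (m in rule$high) ok <- ok && med[m] > thresholds[m]
  for (m in rule$low) ok <- ok && med[m] <= thresholds[m]
  for (m in rule$mid) ok <- ok && abs(med[m] - thresholds[m]) <= mid_band
  isTRUE(ok)
}

#' Annotate events via SOM metaclusters and a rule table
#'
#' Merges the SOM codebook into `k` metaclusters by average-linkage
#' hierarchical clustering, computes per-metacluster marker medians over the
#' member events, and labels each metacluster with the first matching rule.
#' Rules compare medians against per-marker thresholds (Gaussian-mixture
#' midpoints from [marker_thresholds()] unless supplied). Metaclusters
#' matching no rule are labelled `"unassigned"` with a warning.
#'
#' @param data events x markers matrix (transformed scale) used for median
#'   computation and thresholds.
#' @param model a [train_som()] fit trained on (a subset of the columns of)
#'   `data`.
#' @param k number of metaclusters (default 10). Over-clustering relative to
#'   the number of expected labels is deliberate: several metaclusters may
#'   share a label, whereas a tree cut at exactly the expected number can
#'   force two genuine categories into one metacluster.
#' @param rules ordered rule list (default [default_phase_rules()]).
#' @param thresholds optional named threshold vector.
#' @param mid_band half-width of the "mid" (intermediate-expression) band
#'   around the threshold (default 0.18 scaled units).
#' @param seed seed forwarded to [marker_thresholds()].
#' @return list of class `metacluster_annotation`: `labels` (per event),
#'   `metacluster` (per event), `medians` (metacluster x marker),
#'   `cluster_labels`, `thresholds`.
#' @export
metacluster_annotate <- function(data, model, k = 10,
                                 rules = default_phase_rules(),
                                 thresholds = NULL, mid_band = 0.18,
                                 seed = 1) {
  data <- as.matrix(data)
  train_markers <- colnames(model$codebook)
  nodes <- som_map(model, data[, train_markers, drop = FALSE])
  hc <- hclust(dist(model$codebook), method = "average")
  node2meta <- cutree(hc, k = k)
  meta <- node2meta[nodes]
  rule_markers <- unique(unlist(lapply(rules, function(r)
    c(r$high, r$low, r$mid))))
  missing_m <- setdiff(rule_markers, colnames(data))
  if (length(missing_m)) {
    stop("rules reference markers absent from data: ",
         paste(missing_m, collapse = ", "))
  }
  if (is.null(thresholds)) {
    thresholds <- marker_thresholds(data, markers = rule_markers, seed = seed)
  }
  med <- t(vapply(seq_len(k), function(mc) {
    apply(data[meta == mc, , drop = FALSE], 2, median)
  }, numeric(ncol(data))))
  colnames(med) <- colnames(data)
  cluster_labels <- vapply(seq_len(k), function(mc) {
    for (rule in rules) {
      if (rule_matches(med[mc, ], rule, thresholds, mid_band)) {
        return(rule$label)
      }
    }
    "unassigned"
  }, character(1))
  if (any(cluster_labels == "unassigned")) {
    warning(sum(cluster_labels == "unassigned"),
            " metacluster(s) matched no rule and were labelled 'unassigned'")
  }
  structure(list(labels = cluster_labels[meta], metacluster = meta,
                 medians = med, cluster_labels = cluster_labels,
                 thresholds = thresholds),
            class = "metacluster_annotation")
}

#' Conventional bi-axial gating of events
#'
#' Deterministic per-event rectangular gating applying the same ordered
#' rules as [metacluster_annotate()] to each event's marker values (rather
#' than metacluster medians): the first matching rule wins.
#'
#' @param data events x markers matrix (transformed scale).
#' @param rules ordered rule list (default [default_phase_rules()]).
#' @param thresholds named per-marker thresholds (computed from the data via
#'   [marker_thresholds()] when omitted).
#' @param mid_band as in [metacluster_annotate()].
#' @param seed seed forwarded to [marker_thresholds()].
#' @return character vector of per-event labels.
#' @export
biaxial_gate <- function(data, rules = default_phase_rules(),
                         thresholds = NULL, mid_band = 0.18, seed = 1) {
  data <- as.matrix(data)
  rule_markers <- unique(unlist(lapply(rules, function(r)
    c(r$high, r$low, r$mid))))
  if (is.null(thresholds)) {
    thresholds <- marker_thresholds(data, markers = rule_markers, seed = seed)
  }
  labels <- rep(NA_character_, nrow(data))
  for (rule in rules) {
    ok <- rep(TRUE, nrow(data))
    for (m in rule$high) ok <- ok & data[, m] > thresholds[m]
    for (m in rule$low) ok <- ok & data[, m] <= thresholds[m]
    for (m in rule$mid) ok <- ok & abs(data[, m] - thresholds[m]) <= mid_band
    labels[is.na(labels) & ok] <- rule$label
  }
  labels[is.na(labels)] <- "unassigned"
  labels
}

#' Phase-distribution tests per population
#'
#' Builds condition x phase count tables (per population when population
#' labels are given) and applies the chi-squared homogeneity test with
#' adjusted standardized residuals. Apoptotic and dead events are collapsed
#' into a single `apoptotic/dead` category by default, giving the canonical
#' six categories (five cycle phases plus apoptotic/dead) and hence df = 5
#' for a two-condition comparison; a 5-population comparison has df = 4.
#'
#' @param labels per-event phase labels.
#' @param condition per-event condition labels (>= 2 conditions).
#' @param population optional per-event population labels; tests are run
#'   within each population.
#' @param collapse_dead collapse `apoptotic` and `dead` labels into
#'   `apoptotic/dead` (default `TRUE`).
#' @return list per population: `counts` (condition x phase) and `test`
#'   (a [chisq_homogeneity()] result). Populations absent in some condition
#'   are skipped with a warning.
#' @export
phase_distribution_test <- function(labels, condition, population = NULL,
                                    collapse_dead = TRUE) {
  if (length(unique(condition)) < 2L) stop("need >= 2 conditions")
  if (is.null(population)) population <- rep("all", length(labels))
  stopifnot(length(labels) == length(condition),
            length(labels) == length(population))
  if (collapse_dead) {
    labels[labels %in% c("apoptotic", "dead")] <- "apoptotic/dead"
  }
  out <- list()
  for (pop in unique(population)) {
    sel <- population == pop
    tab <- table(condition = condition[sel], phase = labels[sel])
    if (nrow(tab) < length(unique(condition)) || any(rowSums(tab) == 0)) {
      warning("population '", pop, "' absent in some condition; skipped")
      next
    }
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    out[[pop]] <- list(counts = tab, test = chisq_homogeneity(tab))
  }
  out
}
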