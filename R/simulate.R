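#' Configuration for the layered-tissue simulator
#'
#' Defines the experimental conditions the simulator emulates: a developing
#' ventricular wall sampled at several stages, with epicardial, myocardial and
#' endocardial lineages laid out in anatomical layers, profiled both as
#' dissociated single cells and as Visium-style barcoded spots (55 um spots at
#' 110 um pitch, each mixing 10-20 cells).
#'
#' Counts are negative binomial per gene with lognormal library-size factors.
#' Each cell type elevates its marker genes by `marker_log_fc` on the
#' natural-log scale; each lineage carries a maturity program whose genes
#' shift linearly (slope `maturity_log_slope` on the log-mean scale) with a
#' latent differentiation time in [0, 1]. Mitochondrial genes carry an "MT-"
#' name prefix.
#'
#' @param n_stages number of developmental stages (default 4).
#' @param layers ordered anatomical layer names, outer to inner.
#' @param grid_shape integer c(rows, cols) of the spot lattice.
#' @param spot_diameter_um,spot_pitch_um spot geometry in micrometres;
#'   pitch must be >= diameter.
#' @param cells_per_spot_range integer interval of cells mixed per spot.
#' @param n_cell_types number of cell types.
#' @param markers_per_type marker genes planted per type.
#' @param n_genes total genes; must be >= n_cell_types * markers_per_type.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial.
#' @param nb_dispersion negative-binomial size parameter (smaller = noisier).
#' @param library_size_lognormal c(meanlog, sdlog) of per-cell library-size
#'   factors.
#' @param batch_effect_sd sd of a per-stage lognormal gene factor (default 0:
#'   stages share one technical batch).
#' @param seed integer seed; all simulator randomness derives from it.
#' @param n_cells number of reference cells across all stages.
#' @param marker_log_fc natural-log fold elevation of a type's markers.
#' @param n_maturity_genes latent-time-responsive genes per lineage.
#' @param maturity_log_slope natural-log-scale slope of the maturity program
#'   over the latent-time interval.
#' @param qc_low_gene_fraction,qc_high_mito_fraction fractions of cells
#'   planted as deliberate QC violators (few detected genes / high
#'   mitochondrial content).
#' @param capture_rate per-transcript binomial capture probability when
#'   pooling cells into spots (1 = lossless pooling).
#' @param layer_band_fractions fractions of lattice rows assigned to each
#'   layer, outer to inner.
#' @param layer_latent_sd sd of the latent-time preference kernel used when
#'   sampling cells into spots. Each cell type's latent preference per layer
#'   is derived from its own lineage segment: the layers containing a type
#'   (outer to inner) prefer progressively later cells within that type's
#'   latent window, emulating maturation with tissue depth.
#' @param cell_type_names optional type names; defaults to heart cell types
#'   when `n_cell_types == 8`, generic names otherwise.
#' @param type_lineages optional named vector mapping type ->
#'   "epicardial"/"myocardial"/"endocardial"/"none".
#' @param layer_composition optional layers x types matrix of expected type
#'   proportions per layer; rows must sum to 1.
#'
#' @return A list of class `TissueConfig`.
#' @export
tissue_config <- function(n_stages = 4L,
                          layers = c("epicardium", "compact_myocardium",
                                     "trabecular_myocardium", "endocardium",
                                     "valve"),
                          grid_shape = c(20L, 20L),
                          spot_diameter_um = 55,
                          spot_pitch_um = 110,
                          cells_per_spot_range = c(10L, 20L),
                          n_cell_types = 8L,
                          markers_per_type = 25L,
                          n_genes = 600L,
                          mito_gene_fraction = 0.05,
                          nb_dispersion = 2,
                          library_size_lognormal = c(meanlog = log(2500),
                                                     sdlog = 0.3),
                          batch_effect_sd = 0,
                          seed = 1L,
                          n_cells = 1200L,
                          marker_log_fc = 2.0,
                          n_maturity_genes = 60L,
                          maturity_log_slope = 2.0,
                          qc_low_gene_fraction = 0,
                          qc_high_mito_fraction = 0,
                          capture_rate = 1.0,
                          layer_band_fractions = NULL,
                          layer_latent_sd = 0.12,
                          cell_type_names = NULL,
                          type_lineages = NULL,
                          layer_composition = NULL) {
  if (cells_per_spot_range[1] < 1)
    stop("cells_per_spot_range lower bound must be >= 1")
  if (spot_pitch_um < spot_diameter_um)
    stop("spot_pitch_um must be >= spot_diameter_um")
  if (n_genes < n_cell_types * markers_per_type)
    stop("n_genes (", n_genes, ") < n_cell_types * markers_per_type (",
         n_cell_types * markers_per_type, ")")
  if (capture_rate <= 0 || capture_rate > 1)
    stop("capture_rate must be in (0, 1]")

  if (is.null(cell_type_names)) {
    cell_type_names <- if (n_cell_types == 8L) {
      c("epicardial", "epi_derived_fibroblast", "compact_cardiomyocyte",
        "trabecular_cardiomyocyte", "endocardial", "valve_interstitial",
        "immune", "erythrocyte")
    } else sprintf("type%02d", seq_len(n_cell_types))
  }
  stopifnot(length(cell_type_names) == n_cell_types)
  if (is.null(type_lineages)) {
    type_lineages <- if (n_cell_types == 8L) {
      stats::setNames(c("epicardial", "epicardial", "myocardial", "myocardial",
                        "endocardial", "endocardial", "none", "none"),
                      cell_type_names)
    } else {
      stats::setNames(rep_len(c("epicardial", "myocardial", "endocardial"),
                              n_cell_types), cell_type_names)
    }
  }
  if (is.null(layer_band_fractions)) {
    layer_band_fractions <- if (length(layers) == 5L)
      c(0.15, 0.30, 0.30, 0.15, 0.10)
    else rep(1 / length(layers), length(layers))
  }
  stopifnot(length(layer_band_fractions) == length(layers))
  if (is.null(layer_composition)) {
    layer_composition <- default_layer_composition(layers, cell_type_names)
  }
  stopifnot(nrow(layer_composition) == length(layers),
            ncol(layer_composition) == n_cell_types)
  if (any(abs(rowSums(layer_composition) - 1) > 1e-8))
    stop("layer_composition rows must sum to 1")
  rownames(layer_composition) <- layers
  colnames(layer_composition) <- cell_type_names

  structure(list(
    n_stages = as.integer(n_stages), layers = layers,
    grid_shape = as.integer(grid_shape),
    spot_diameter_um = spot_diameter_um, spot_pitch_um = spot_pitch_um,
    cells_per_spot_range = as.integer(cells_per_spot_range),
    n_cell_types = as.integer(n_cell_types),
    markers_per_type = as.integer(markers_per_type),
    n_genes = as.integer(n_genes),
    mito_gene_fraction = mito_gene_fraction,
    nb_dispersion = nb_dispersion,
    library_size_lognormal = library_size_lognormal,
    batch_effect_sd = batch_effect_sd, seed = as.integer(seed),
    n_cells = as.integer(n_cells), marker_log_fc = marker_log_fc,
    n_maturity_genes = as.integer(n_maturity_genes),
    maturity_log_slope = maturity_log_slope,
    qc_low_gene_fraction = qc_low_gene_fraction,
    qc_high_mito_fraction = qc_high_mito_fraction,
    capture_rate = capture_rate,
    layer_band_fractions = layer_band_fractions,
    layer_latent_sd = layer_latent_sd,
    cell_type_names = cell_type_names,
    type_lineages = type_lineages,
    layer_composition = layer_composition), class = "TissueConfig")
}

# Default layer -> type composition. For the 8 built-in heart types each
# anatomical layer is dominated by its resident lineage; otherwise each type
# gets a "home" layer round-robin and home types are weighted 3:1.
default_layer_composition <- function(layers, types) {
  L <- length(layers); K <- length(types)
  if (K == 8L && L == 5L) {
    comp <- rbind(
      c(.60, .20, .10, 0,   0,   0,   .05, .05),
      c(.05, .15, .60, .10, 0,   0,   .05, .05),
      c(0,   0,   .10, .55, .20, 0,   .05, .10),
      c(0,   0,   0,   .15, .70, .05, .05, .05),
      c(0,   0,   0,   0,   .15, .80, .05, 0))
  } else {
    home <- ((seq_len(K) - 1L) %% L) + 1L
    comp <- matrix(0, L, K)
    for (l in seq_len(L)) {
      w <- ifelse(home == l, 3, 1)
      comp[l, ] <- w / sum(w)
    }
  }
  dimnames(comp) <- list(layers, types)
  comp
}

#' Simulate a single-cell reference with ground truth
#'
#' Draws `n_cells` cells across the configured stages. Each cell gets a type,
#' a lineage-specific latent differentiation time, and negative-binomial
#' counts whose expected profile reflects its type's markers and its
#' lineage's maturity program. Optional fractions of cells are planted as QC
#' violators (fewer than 200 detected genes, or mitochondrial content pushed
#' above 20%) so downstream filtering can be verified against truth.
#'
#' @param config a `TissueConfig`.
#' @return list with `cells` (an [expression_matrix()] of kind "cells") and
#'   `truth` (partial `TruthBundle`: per-cell `cell_type`,
#'   `cell_latent_time`, `cell_stage`, `lineage`, `qc_violation`, plus
#'   `marker_panels`, `maturity_genes` and the types x genes expectation
#'   matrix `type_expected` evaluated at latent time 0.5).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "TissueConfig"))
  if (config$n_genes < config$n_cell_types * config$markers_per_type)
    stop("n_genes too small for the requested marker panels")
  set.seed(config$seed)
  G <- config$n_genes
  K <- config$n_cell_types
  types <- config$cell_type_names

  n_mito <- max(1L, round(config$mito_gene_fraction * G))
  gene_names <- c(sprintf("MT-G%03d", seq_len(n_mito)),
                  sprintf("GENE%04d", seq_len(G - n_mito)))
  gene_ids <- sprintf("SYNG%05d", seq_len(G))
  non_mito <- which(!startsWith(gene_names, "MT-"))

  # marker panels: disjoint blocks of non-mito genes, one per type
  marker_idx <- matrix(non_mito[seq_len(K * config$markers_per_type)],
                       nrow = config$markers_per_type)
  marker_panels <- stats::setNames(
    lapply(seq_len(K), function(k) gene_names[marker_idx[, k]]), types)

  # maturity programs: per lineage, genes outside all marker panels,
  # half increasing and half decreasing with latent time
  lineages <- setdiff(unique(config$type_lineages), "none")
  pool <- setdiff(non_mito, as.vector(marker_idx))
  maturity_genes <- list()
  for (ln in lineages) {
    take <- pool[seq_len(min(config$n_maturity_genes, length(pool)))]
    pool <- setdiff(pool, take)
    dir <- rep_len(c(1, -1), length(take))
    maturity_genes[[ln]] <- data.frame(gene = gene_names[take], idx = take,
                                       direction = dir)
  }

  base_rate <- rgamma(G, shape = 0.8, rate = 1) + 0.05
  # mitochondrial genes get a modest boost so healthy cells sit near ~5% mito
  base_rate[seq_len(n_mito)] <- base_rate[seq_len(n_mito)] * 2

  type_log_boost <- matrix(0, K, G)
  for (k in seq_len(K)) type_log_boost[k, marker_idx[, k]] <- config$marker_log_fc

  # stage composition drift: early types wane, late types wax
  stage_w <- sapply(seq_len(config$n_stages), function(s) {
    early <- seq_len(K) <= ceiling(K / 2)
    w <- ifelse(early, config$n_stages - s + 1, s)
    w / sum(w)
  })
  stage_w <- matrix(stage_w, nrow = K)

  # Each lineage orders its member types along differentiation as segments
  # of one continuum: type k of m has latent-time centre (k - 0.5)/m and
  # occupies the window [(k-1)/m - 0.1, k/m + 0.1] (clipped). Marker
  # programs shift smoothly with latent time: a lineage cell at latent l
  # expresses type k's markers with boost marker_log_fc * exp(-((l-c_k)/tau)^2/2),
  # tau = 0.5/m, so programs cross-fade at segment boundaries instead of
  # stepping -- the label is a discretization of a continuous trajectory.
  type_window <- matrix(c(0, 1), config$n_cell_types, 2, byrow = TRUE,
                        dimnames = list(types, c("lo", "hi")))
  type_center <- rep(NA_real_, config$n_cell_types)
  names(type_center) <- types
  type_tau <- type_center
  for (ln in lineages) {
    members <- names(config$type_lineages)[config$type_lineages == ln]
    m <- length(members)
    for (k in seq_len(m)) {
      type_window[members[k], ] <- c(max(0, (k - 1) / m - 0.1),
                                     min(1, k / m + 0.1))
      type_center[members[k]] <- (k - 0.5) / m
      type_tau[members[k]] <- if (m == 1) Inf else 0.5 / m
    }
  }

  n_cells <- config$n_cells
  cell_stage <- sort(rep_len(seq_len(config$n_stages), n_cells))
  cell_type <- character(n_cells)
  latent <- numeric(n_cells)
  for (s in seq_len(config$n_stages)) {
    idx <- which(cell_stage == s)
    cell_type[idx] <- sample(types, length(idx), replace = TRUE,
                             prob = stage_w[, s])
    ctr <- (s - 0.5) / config$n_stages
    s_lo <- max(0, ctr - 0.3); s_hi <- min(1, ctr + 0.3)
    for (i in idx) {
      lo <- max(s_lo, type_window[cell_type[i], "lo"])
      hi <- min(s_hi, type_window[cell_type[i], "hi"])
      if (lo >= hi) {   # stage and type windows disjoint: type window wins
        lo <- type_window[cell_type[i], "lo"]
        hi <- type_window[cell_type[i], "hi"]
      }
      latent[i] <- runif(1, lo, hi)
    }
  }
  lineage <- unname(config$type_lineages[cell_type])

  lib <- rlnorm(n_cells, config$library_size_lognormal[1],
                config$library_size_lognormal[2])
  batch_fac <- matrix(1, config$n_stages, G)
  if (config$batch_effect_sd > 0)
    batch_fac <- matrix(rlnorm(config$n_stages * G, 0, config$batch_effect_sd),
                        config$n_stages, G)

  members_of <- lapply(lineages, function(ln) {
    which(unname(config$type_lineages[types]) == ln)
  })
  names(members_of) <- lineages

  counts <- matrix(0L, G, n_cells)
  k_of <- match(cell_type, types)
  for (i in seq_len(n_cells)) {
    ln <- lineage[i]
    if (ln == "none") {
      lograte <- log(base_rate) + type_log_boost[k_of[i], ]
    } else {
      lograte <- log(base_rate)
      for (k in members_of[[ln]]) {
        w <- exp(-0.5 * ((latent[i] - type_center[k]) / type_tau[k])^2)
        lograte <- lograte + type_log_boost[k, ] * w
      }
      mg <- maturity_genes[[ln]]
      lograte[mg$idx] <- lograte[mg$idx] +
        config$maturity_log_slope * (latent[i] - 0.5) * mg$direction
    }
    rate <- exp(lograte) * batch_fac[cell_stage[i], ]
    mu <- lib[i] * rate / sum(rate)
    counts[, i] <- if (is.finite(config$nb_dispersion)) {
      rnbinom(G, size = config$nb_dispersion, mu = mu)
    } else rpois(G, mu)
  }

  qc_violation <- rep("none", n_cells)
  n_low <- round(config$qc_low_gene_fraction * n_cells)
  n_hi <- round(config$qc_high_mito_fraction * n_cells)
  if (n_low + n_hi > 0) {
    vio <- sample(n_cells, n_low + n_hi)
    for (i in vio[seq_len(n_low)]) {
      keep <- sample(G, 120L)
      counts[-keep, i] <- 0L
      qc_violation[i] <- "low_genes"
    }
    if (n_hi > 0) for (i in vio[n_low + seq_len(n_hi)]) {
      tot_nm <- sum(counts[non_mito, i])
      counts[seq_len(n_mito), i] <-
        as.integer(ceiling(0.45 * tot_nm / n_mito))
      qc_violation[i] <- "high_mito"
    }
  }

  # expected relative-rate profiles (no sampling noise), evaluated at each
  # type's latent-time centre; used by expectation-level marker checks
  type_expected <- t(vapply(seq_len(K), function(k) {
    ln <- unname(config$type_lineages[types[k]])
    lr <- log(base_rate)
    if (ln == "none") {
      lr <- lr + type_log_boost[k, ]
    } else {
      for (k2 in members_of[[ln]]) {
        w <- exp(-0.5 * ((type_center[k] - type_center[k2]) / type_tau[k2])^2)
        lr <- lr + type_log_boost[k2, ] * w
      }
    }
    r <- exp(lr)
    r / sum(r)
  }, numeric(G)))
  dimnames(type_expected) <- list(types, gene_names)

  obs_ids <- sprintf("CELL%05d", seq_len(n_cells))
  cells <- expression_matrix(counts, gene_ids = gene_ids,
                             gene_names = gene_names, obs_ids = obs_ids,
                             obs_meta = data.frame(
                               stage = paste0("stage", cell_stage),
                               row.names = obs_ids),
                             kind = "cells")
  rownames(cells$counts) <- gene_names  # symbols are the working row names

  truth <- structure(list(
    cell_id = obs_ids,
    cell_type = cell_type,
    cell_latent_time = latent,
    cell_stage = paste0("stage", cell_stage),
    lineage = lineage,
    qc_violation = qc_violation,
    marker_panels = marker_panels,
    maturity_genes = maturity_genes,
    type_latent_window = type_window,
    type_latent_center = type_center,
    type_expected = type_expected), class = "TruthBundle")
  list(cells = cells, truth = truth)
}

#' Build the lattice layer map for a configuration
#'
#' Rows of the spot lattice are assigned to anatomical layers in horizontal
#' bands, outer layer first, with band heights proportional to
#' `layer_band_fractions`.
#'
#' @param config a `TissueConfig`.
#' @return character matrix of shape `grid_shape` with layer names.
#' @export
make_layer_map <- function(config) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cuts <- round(cumsum(config$layer_band_fractions) /
                  sum(config$layer_band_fractions) * nr)
  row_layer <- character(nr)
  lo <- 1L
  for (j in seq_along(config$layers)) {
    if (cuts[j] >= lo) row_layer[lo:cuts[j]] <- config$layers[j]
    lo <- cuts[j] + 1L
  }
  row_layer[row_layer == ""] <- config$layers[length(config$layers)]
  matrix(rep(row_layer, nc), nr, nc)
}

#' Simulate Visium-style tissue spots by pooling reference cells
#'
#' Each lattice spot draws 10-20 constituent cells (uniformly within the
#' configured range) from the reference, with type proportions set by its
#' layer's composition row and a preference for cells whose latent time
#' matches the layer's maturation stage. Spot counts are exactly the sum of
#' constituent-cell counts, optionally followed by binomial downsampling at
#' `capture_rate`. Planted QC-violator cells are never sampled into spots.
#'
#' @param config a `TissueConfig`.
#' @param reference the `cells` ExpressionMatrix from [simulate_reference()].
#' @param truth the partial `TruthBundle` from [simulate_reference()].
#' @param layer_map optional character matrix of layer names; defaults to
#'   [make_layer_map()]. Must match `grid_shape`.
#' @return list with `spots` (ExpressionMatrix of kind "spots", obs_meta
#'   carrying `array_row`, `array_col`, `in_tissue`, `layer`) and `truth`
#'   (completed `TruthBundle` adding `spot_id`, `spot_layer`,
#'   `spot_composition`, `spot_mean_latent_time`, `constituent_cells`).
#' @export
simulate_tissue <- function(config, reference, truth, layer_map = NULL) {
  stopifnot(inherits(config, "TissueConfig"),
            inherits(reference, "ExpressionMatrix"),
            inherits(truth, "TruthBundle"))
  if (is.null(layer_map)) layer_map <- make_layer_map(config)
  if (!all(dim(layer_map) == config$grid_shape))
    stop("layer_map shape ", paste(dim(layer_map), collapse = "x"),
         " != grid_shape ", paste(config$grid_shape, collapse = "x"))
  set.seed(config$seed + 1L)

  types <- config$cell_type_names
  eligible <- which(truth$qc_violation == "none")
  cells_by_type <- split(eligible, truth$cell_type[eligible])
  counts <- reference$counts

  # Per-layer latent-time preference for each type, derived from the type's
  # lineage segment: the layers containing a type, outer to inner, prefer
  # progressively later cells within its latent window (maturation with
  # tissue depth). Types absent from a layer have no preference there.
  windows <- truth$type_latent_window
  if (is.null(windows))
    windows <- matrix(c(0, 1), length(types), 2, byrow = TRUE,
                      dimnames = list(types, c("lo", "hi")))
  latent_pref <- matrix(NA_real_, length(config$layers), length(types),
                        dimnames = list(config$layers, types))
  for (k in seq_along(types)) {
    lays <- which(config$layer_composition[, k] > 0)
    win <- windows[types[k], ]
    for (j in seq_along(lays)) {
      f <- (j - 0.5) / length(lays)
      latent_pref[lays[j], k] <- win[["lo"]] + f * (win[["hi"]] - win[["lo"]])
    }
  }

  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  n_spots <- nr * nc
  rng <- config$cells_per_spot_range
  spot_ids <- character(n_spots)
  arr_row <- integer(n_spots); arr_col <- integer(n_spots)
  spot_layer <- character(n_spots)
  comp <- matrix(0, n_spots, length(types),
                 dimnames = list(NULL, types))
  mean_latent <- numeric(n_spots)
  constituents <- vector("list", n_spots)
  spot_counts <- matrix(0, nrow(counts), n_spots)

  s <- 0L
  for (col in seq_len(nc)) for (row in seq_len(nr)) {
    s <- s + 1L
    arr_row[s] <- row - 1L; arr_col[s] <- col - 1L
    spot_ids[s] <- sprintf("SPOT_%03d_%03d", row - 1L, col - 1L)
    layer <- layer_map[row, col]
    spot_layer[s] <- layer
    n_cell <- sample(rng[1]:rng[2], 1L)
    draw <- as.vector(rmultinom(1, n_cell, config$layer_composition[layer, ]))
    chosen <- integer(0)
    for (k in which(draw > 0)) {
      pool <- cells_by_type[[types[k]]]
      if (is.null(pool) || !length(pool)) next
      ctr <- latent_pref[layer, k]
      w <- stats::dnorm(truth$cell_latent_time[pool], ctr,
                        config$layer_latent_sd) + 1e-12
      chosen <- c(chosen, pool[sample.int(length(pool), draw[k],
                                          replace = TRUE, prob = w)])
    }
    constituents[[s]] <- chosen
    tab <- table(factor(truth$cell_type[chosen], levels = types))
    comp[s, ] <- as.numeric(tab) / length(chosen)
    mean_latent[s] <- mean(truth$cell_latent_time[chosen])
    v <- Matrix::rowSums(counts[, chosen, drop = FALSE])
    if (config$capture_rate < 1)
      v <- rbinom(length(v), size = as.integer(v), prob = config$capture_rate)
    spot_counts[, s] <- v
  }

  spots <- expression_matrix(spot_counts,
                             gene_ids = reference$gene_ids,
                             gene_names = reference$gene_names,
                             obs_ids = spot_ids,
                             obs_meta = data.frame(
                               array_row = arr_row, array_col = arr_col,
                               in_tissue = rep(TRUE, n_spots),
                               layer = spot_layer,
                               row.names = spot_ids),
                             kind = "spots")
  rownames(spots$counts) <- reference$gene_names

  truth$spot_id <- spot_ids
  truth$spot_layer <- spot_layer
  rownames(comp) <- spot_ids
  truth$spot_composition <- comp
  truth$spot_mean_latent_time <- mean_latent
  truth$constituent_cells <- stats::setNames(
    lapply(constituents, function(i) truth$cell_id[i]), spot_ids)
  list(spots = spots, truth = truth)
}

#' Write a TruthBundle to CSV files
#'
#' Emits `truth_cells.csv`, `truth_spots.csv`, `truth_composition.csv`,
#' `truth_constituents.csv` and `truth_markers.csv` under `dir`. The tables
#' round-trip losslessly through [read_truth()].
#'
#' @param truth a `TruthBundle` (partial or completed).
#' @param dir output directory, created if absent.
#' @return invisibly, the vector of files written.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "TruthBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  files <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  w(data.frame(cell_id = truth$cell_id, cell_type = truth$cell_type,
               cell_latent_time = truth$cell_latent_time,
               cell_stage = truth$cell_stage, lineage = truth$lineage,
               qc_violation = truth$qc_violation), "truth_cells.csv")
  w(data.frame(type = rep(names(truth$marker_panels),
                          lengths(truth$marker_panels)),
               gene = unlist(truth$marker_panels, use.names = FALSE)),
    "truth_markers.csv")
  if (!is.null(truth$spot_id)) {
    w(data.frame(spot_id = truth$spot_id, spot_layer = truth$spot_layer,
                 spot_mean_latent_time = truth$spot_mean_latent_time),
      "truth_spots.csv")
    w(data.frame(spot_id = truth$spot_id,
                 truth$spot_composition, check.names = FALSE),
      "truth_composition.csv")
    w(data.frame(spot_id = rep(names(truth$constituent_cells),
                               lengths(truth$constituent_cells)),
                 cell_id = as.character(unlist(truth$constituent_cells,
                                               use.names = FALSE))),
      "truth_constituents.csv")
  }
  invisible(files)
}

#' Read a TruthBundle written by [write_truth()]
#'
#' @param dir directory containing the truth CSVs.
#' @return a `TruthBundle` (marker panels and per-cell fields always;
#'   spot-level fields when present on disk). The expectation matrix and
#'   maturity-gene tables are in-memory artifacts and are not round-tripped.
#' @export
read_truth <- function(dir) {
  cells <- utils::read.csv(file.path(dir, "truth_cells.csv"),
                           colClasses = c(cell_id = "character"))
  mk <- utils::read.csv(file.path(dir, "truth_markers.csv"))
  truth <- structure(list(
    cell_id = cells$cell_id, cell_type = cells$cell_type,
    cell_latent_time = cells$cell_latent_time,
    cell_stage = cells$cell_stage, lineage = cells$lineage,
    qc_violation = cells$qc_violation,
    marker_panels = split(mk$gene, mk$type)), class = "TruthBundle")
  sp <- file.path(dir, "truth_spots.csv")
  if (file.exists(sp)) {
    spots <- utils::read.csv(sp, colClasses = c(spot_id = "character"))
    truth$spot_id <- spots$spot_id
    truth$spot_layer <- spots$spot_layer
    truth$spot_mean_latent_time <- spots$spot_mean_latent_time
    compdf <- utils::read.csv(file.path(dir, "truth_composition.csv"),
                              check.names = FALSE,
                              colClasses = c(spot_id = "character"))
    comp <- as.matrix(compdf[, -1, drop = FALSE])
    rownames(comp) <- compdf$spot_id
    truth$spot_composition <- comp
    con <- utils::read.csv(file.path(dir, "truth_constituents.csv"),
                           colClasses = "character")
    truth$constituent_cells <- split(con$cell_id, con$spot_id)[truth$spot_id]
    if (length(truth$constituent_cells) == 0)
      truth$constituent_cells <- stats::setNames(list(), character(0))
  }
  truth
}
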