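#' Compartment vocabulary for pathologist annotations
#'
#' The five pathological compartment labels used for annotation polygons and
#' spot-level annotation transfer.
#'
#' @return character vector of the five compartment labels.
#' @export
ect_compartments <- function() {
  c("Peritumor stroma", "Intratumor stroma", "Cancer cells",
    "Lymphocyte aggregates", "Normal ducts and lobules")
}

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic multi-section generator.
#' Defaults replicate the design of the breast-cancer Visium study the package
#' targets: 17 sections of ~2,000 spots on a 55 µm-spot hexagonal lattice,
#' 37 deconvolved cell types and states, 11 spatial niches, 10 co-occurrence
#' (EcoCellType) blocks, and an expected 15 cells per spot.
#'
#' @param n_sections number of tissue sections (batches).
#' @param spots_per_section spots per section on the hexagonal lattice.
#' @param spot_diameter spot diameter in µm (Visium: 55).
#' @param n_cell_types number of deconvolved cell types/states.
#' @param cancer_type_names names of the cancer cell types (must be among the
#'   generated cell-type names; default the first type, "Cancer cells").
#' @param n_niches number of planted spatial niches.
#' @param niche_center_concentration Dirichlet precision of per-spot
#'   compositions around their niche centre; larger = tighter niches.
#' @param batch_shift_sd sd of the per-section, per-cell-type multiplicative
#'   log-normal batch factor (0 = no batch effect).
#' @param spatial_smoothness contiguity of niche domains: spots are assigned to
#'   the nearest niche seed after positional jitter of sd
#'   `lattice_pitch / spatial_smoothness`; larger = cleaner domains.
#' @param total_cells_per_spot expected number of cells per spot.
#' @param n_ect_blocks number of planted cell-type co-occurrence blocks.
#' @param seed integer seed (< 2^31); identical seeds give identical output.
#' @return object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_sections = 17L,
                       spots_per_section = 2000L,
                       spot_diameter = 55,
                       n_cell_types = 37L,
                       cancer_type_names = NULL,
                       n_niches = 11L,
                       niche_center_concentration = 150,
                       batch_shift_sd = 0.3,
                       spatial_smoothness = 4,
                       total_cells_per_spot = 15,
                       n_ect_blocks = 10L,
                       seed = 1L) {
  cfg <- list(
    n_sections = as.integer(n_sections),
    spots_per_section = as.integer(spots_per_section),
    spot_diameter = spot_diameter,
    n_cell_types = as.integer(n_cell_types),
    n_niches = as.integer(n_niches),
    niche_center_concentration = niche_center_concentration,
    batch_shift_sd = batch_shift_sd,
    spatial_smoothness = spatial_smoothness,
    total_cells_per_spot = total_cells_per_spot,
    n_ect_blocks = as.integer(n_ect_blocks),
    seed = as.integer(seed)
  )
  cfg$cell_types <- sim_cell_type_names(cfg$n_cell_types)
  cfg$cancer_type_names <- cancer_type_names %||% cfg$cell_types[1L]

  if (cfg$n_sections < 1L) stop2("n_sections must be >= 1")
  if (cfg$spots_per_section < 1L) stop2("spots_per_section must be >= 1")
  if (cfg$spot_diameter <= 0) stop2("spot_diameter must be > 0")
  if (cfg$n_cell_types < 2L) stop2("n_cell_types must be >= 2")
  if (cfg$n_niches < 1L) stop2("n_niches must be >= 1")
  if (cfg$n_niches > cfg$spots_per_section)
    stop2("n_niches (", cfg$n_niches, ") exceeds spots_per_section (",
          cfg$spots_per_section, ")")
  if (cfg$n_ect_blocks < 1L || cfg$n_ect_blocks > cfg$n_cell_types)
    stop2("n_ect_blocks must be in [1, n_cell_types]")
  if (!all(cfg$cancer_type_names %in% cfg$cell_types))
    stop2("cancer_type_names not among cell types: ",
          paste(setdiff(cfg$cancer_type_names, cfg$cell_types), collapse = ", "))
  if (cfg$niche_center_concentration <= 0)
    stop2("niche_center_concentration must be > 0")
  if (cfg$batch_shift_sd < 0) stop2("batch_shift_sd must be >= 0")
  if (cfg$spatial_smoothness < 0) stop2("spatial_smoothness must be >= 0")
  if (cfg$total_cells_per_spot <= 0) stop2("total_cells_per_spot must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

sim_cell_type_names <- function(d) {
  c("Cancer cells", sprintf("CellState%02d", seq_len(d - 1L) + 1L))[seq_len(d)]
}

# Centre-to-centre lattice pitch, µm (Visium spacing for 55 µm spots).
sim_lattice_pitch <- function(config) 100

# Global (cross-section) planted structure: ECT block membership, block x niche
# enrichment, per-niche compositional centres. Deterministic in config$seed.
sim_global_structure <- function(config) {
  d <- config$n_cell_types
  b <- config$n_ect_blocks
  k <- config$n_niches
  set.seed(config$seed %% 2147483647)
  membership <- setNames(sample(rep(seq_len(b), length.out = d)), config$cell_types)
  base <- as.vector(rdirichlet(1, rep(5, d)))
  # block niche-enrichment profiles: distinct co-occurrence patterns are the
  # ground truth, so profiles are rejected while they are near-collinear with
  # an accepted block (|cor| > 0.4) or too weak to survive per-type scaling
  block_enrich <- matrix(NA_real_, nrow = b, ncol = k)
  for (i in seq_len(b)) {
    for (try in 1:200) {
      v <- rnorm(k, sd = 1.25)
      strong <- sqrt(sum(v^2)) >= 0.7 * 1.25 * sqrt(k)
      distinct <- i == 1L || k < 3L ||
        max(abs(cor(v, t(block_enrich[seq_len(i - 1L), , drop = FALSE])))) <= 0.4
      if (strong && distinct) break
    }
    block_enrich[i, ] <- v
  }
  type_enrich <- block_enrich[membership, , drop = FALSE] +
    matrix(rnorm(d * k, sd = 0.15), nrow = d, ncol = k)
  centers <- t(base * exp(type_enrich))       # k x d
  centers <- centers / rowSums(centers)
  dimnames(centers) <- list(paste0("niche", seq_len(k)), config$cell_types)
  list(ect_membership = membership, niche_centers = centers,
       base_composition = base)
}

# Hexagonal lattice of n spots: rows of pitch-spaced columns, alternate rows
# offset by pitch/2, row spacing pitch * sqrt(3)/2. Image convention: y grows
# downward.
hex_lattice <- function(n, pitch) {
  ncol_ <- max(1L, ceiling(sqrt(n)))
  nrow_ <- ceiling(n / ncol_)
  row <- rep(seq_len(nrow_) - 1L, each = ncol_)[seq_len(n)]
  col <- rep(seq_len(ncol_) - 1L, times = nrow_)[seq_len(n)]
  cbind(x = col * pitch + (row %% 2L) * pitch / 2,
        y = row * pitch * sqrt(3) / 2)
}

# Spatially contiguous niche labels: nearest-seed Voronoi domains with
# positional jitter controlling boundary raggedness.
sim_niche_field <- function(coords, n_niches, pitch, smoothness,
                            seeds_per_niche = 2L) {
  n <- nrow(coords)
  if (n_niches == 1L) return(rep(1L, n))
  ns <- n_niches * seeds_per_niche
  xr <- range(coords[, 1]); yr <- range(coords[, 2])
  sx <- runif(ns, xr[1], xr[2]); sy <- runif(ns, yr[1], yr[2])
  seed_niche <- rep(seq_len(n_niches), seeds_per_niche)
  jitter_sd <- if (smoothness > 0) pitch / smoothness else pitch * 50
  jx <- coords[, 1] + rnorm(n, sd = jitter_sd)
  jy <- coords[, 2] + rnorm(n, sd = jitter_sd)
  d2 <- outer(jx, sx, "-")^2 + outer(jy, sy, "-")^2
  seed_niche[max.col(-d2, ties.method = "first")]
}

#' Generate synthetic deconvolved sections with ground truth
#'
#' Simulates multi-section spot tables and abundance matrices shaped like
#' posterior-quantile deconvolution output. Each section is a hexagonal lattice
#' of spots; spots are assigned to spatially contiguous niche domains; each
#' spot's composition is a Dirichlet draw around its niche centre, multiplied
#' by a Gamma-distributed total cell count and a per-section, per-cell-type
#' log-normal batch factor. Cell types within an EcoCellType block share their
#' niche-enrichment pattern, so the block structure is recoverable from the
#' niche-mean composition matrix.
#'
#' @param config a [sim_config()].
#' @return list with `sections` (list of `ect_section` objects, see
#'   [new_section()]) and `truth` (list: per-section `niche_labels`,
#'   `ect_membership`, `niche_centers`, `batch_factors`, `config`).
#' @export
generate_sections <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  glob <- sim_global_structure(config)
  pitch <- sim_lattice_pitch(config)
  d <- config$n_cell_types
  k <- config$n_niches
  conc <- config$niche_center_concentration

  set.seed((config$seed + 1L) %% 2147483647)
  batch <- matrix(exp(rnorm(config$n_sections * d, sd = config$batch_shift_sd)),
                  nrow = config$n_sections, ncol = d)
  sections <- vector("list", config$n_sections)
  labels <- vector("list", config$n_sections)
  for (s in seq_len(config$n_sections)) {
    sid <- sprintf("S%02d", s)
    n <- config$spots_per_section
    coords <- hex_lattice(n, pitch)
    niche <- sim_niche_field(coords, k, pitch, config$spatial_smoothness)
    # per-spot Dirichlet composition around the niche centre
    alpha <- glob$niche_centers[niche, , drop = FALSE] * conc
    g <- matrix(rgamma(n * d, shape = pmax(alpha, 1e-8)), nrow = n, ncol = d)
    p <- g / pmax(rowSums(g), .Machine$double.xmin)
    total <- rgamma(n, shape = 25, rate = 25 / config$total_cells_per_spot)
    ab <- p * total
    ab <- sweep(ab, 2L, batch[s, ], `*`)
    spot_ids <- sprintf("%s_spot%04d", sid, seq_len(n))
    dimnames(ab) <- list(spot_ids, config$cell_types)
    sections[[s]] <- new_section(
      section_id = sid, spot_ids = spot_ids, coords = coords,
      spot_diameter = config$spot_diameter, abundance = ab)
    labels[[s]] <- setNames(niche, spot_ids)
  }
  names(sections) <- names(labels) <- vapply(sections, `[[`, "", "section_id")
  list(sections = sections,
       truth = list(niche_labels = labels,
                    ect_membership = glob$ect_membership,
                    niche_centers = glob$niche_centers,
                    batch_factors = batch,
                    config = config))
}

#' Generate annotation polygons from planted niches
#'
#' Builds a pathologist-style annotation layer for one section by mapping each
#' planted niche to a compartment label and covering each spot with its
#' hexagonal lattice cell. The union of a compartment's hexagons covers every
#' spot of its niches, so the true compartment is recoverable by the
#' annotation-transfer rule.
#'
#' @param section an `ect_section`.
#' @param niche_labels integer niche label per spot of the section.
#' @param mapping named character vector: names are niche ids (as character),
#'   values compartment labels from [ect_compartments()].
#' @param pitch lattice pitch in µm; inferred from spot coordinates if `NULL`.
#' @return an `ect_annotations` layer (see [new_annotations()]).
#' @export
generate_annotations <- function(section, niche_labels, mapping, pitch = NULL) {
  stopifnot(inherits(section, "ect_section"))
  if (length(niche_labels) != length(section$spot_ids))
    stop2("niche_labels must have one label per spot")
  niches <- sort(unique(niche_labels))
  if (!all(as.character(niches) %in% names(mapping)))
    stop2("mapping is missing niche ids: ",
          paste(setdiff(as.character(niches), names(mapping)), collapse = ", "))
  if (!all(mapping %in% ect_compartments()))
    stop2("mapping uses labels outside the compartment vocabulary: ",
          paste(setdiff(mapping, ect_compartments()), collapse = ", "))
  if (is.null(pitch)) {
    pitch <- if (nrow(section$coords) >= 2) {
      min(dist(section$coords[seq_len(min(200L, nrow(section$coords))), ,
                              drop = FALSE]))
    } else 2 * section$spot_diameter
  }
  # circumradius of the lattice Voronoi hexagon (apothem = pitch / 2)
  r <- pitch / sqrt(3)
  feats <- lapply(seq_along(section$spot_ids), function(i) {
    list(label = unname(mapping[[as.character(niche_labels[i])]]),
         rings = list(hex_ring(section$coords[i, 1], section$coords[i, 2], r)))
  })
  new_annotations(feats)
}

#' Generate a synthetic cohort with a planted survival effect
#'
#' Simulates per-sample cell-type fraction tables with survival outcomes. Each
#' sample belongs to one of `n_archetypes` compositional archetypes; fractions
#' are Dirichlet draws around the archetype centre. Survival times are
#' exponential with log-hazard linear in the sample's planted EcoCellType
#' fractions (aggregated with the same block membership as
#' [generate_sections()]); censoring is independent exponential.
#'
#' @param config a [sim_config()] (supplies cell types and block membership).
#' @param n_samples number of samples (>= 2).
#' @param effect numeric vector of per-ECT log-hazard coefficients, length
#'   `config$n_ect_blocks`.
#' @param censoring_rate rate of the exponential censoring distribution
#'   (>= 0; 0 disables censoring).
#' @param n_archetypes number of compositional archetypes.
#' @param concentration Dirichlet precision of samples around their archetype.
#' @param baseline_hazard baseline event rate (per unit follow-up time).
#' @param seed integer seed; default derived from `config$seed`.
#' @return list with `table` (data.frame: sample_id, one fraction column per
#'   cell type, time, event, subtype) and `truth` (archetype ids, archetype
#'   centres, ect_membership, effect).
#' @export
generate_cohort <- function(config, n_samples, effect,
                            censoring_rate = 0.08,
                            n_archetypes = 4L,
                            concentration = 50,
                            baseline_hazard = log(2) / 5,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_samples < 2L) stop2("n_samples must be >= 2")
  if (length(effect) != config$n_ect_blocks)
    stop2("effect must have one coefficient per ECT block (",
          config$n_ect_blocks, ")")
  if (censoring_rate < 0) stop2("censoring_rate must be >= 0")
  glob <- sim_global_structure(config)
  d <- config$n_cell_types
  set.seed((seed %||% (config$seed + 101L)) %% 2147483647)

  # archetype centres are planted at the ECT level (subgroups differ in ECT
  # enrichment); within each block, mass is split among member types with one
  # shared proportion vector, so differences survive ECT aggregation
  b <- config$n_ect_blocks
  memb <- glob$ect_membership[config$cell_types]
  ect_weights <- rdirichlet(n_archetypes, rep(0.8, b))
  within <- numeric(d)
  for (e in seq_len(b)) {
    ix <- which(memb == e)
    within[ix] <- as.vector(rdirichlet(1, rep(2, length(ix))))
  }
  arch_centers <- ect_weights[, memb, drop = FALSE] * rep(within, each = n_archetypes)
  arch_centers <- arch_centers / rowSums(arch_centers)
  colnames(arch_centers) <- config$cell_types
  archetype <- sample(seq_len(n_archetypes), n_samples, replace = TRUE)
  frac <- matrix(NA_real_, n_samples, d, dimnames = list(NULL, config$cell_types))
  for (a in seq_len(n_archetypes)) {
    idx <- which(archetype == a)
    if (length(idx))
      frac[idx, ] <- rdirichlet(length(idx),
                                pmax(arch_centers[a, ] * concentration, 1e-3))
  }
  ect_frac <- t(rowsum(t(frac), group = glob$ect_membership[config$cell_types]))
  colnames(ect_frac) <- paste0("ECT", colnames(ect_frac))
  loghaz <- log(baseline_hazard) +
    as.vector(ect_frac %*% effect[as.integer(sub("ECT", "", colnames(ect_frac)))])
  t_event <- rexp(n_samples, rate = exp(loghaz))
  t_cens <- if (censoring_rate > 0) rexp(n_samples, rate = censoring_rate)
            else rep(Inf, n_samples)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  subtype <- sample(c("LumA", "LumB", "HER2", "Basal"), n_samples,
                    replace = TRUE, prob = c(487, 368, 193, 186) / 1234)
  tab <- data.frame(sample_id = sprintf("P%04d", seq_len(n_samples)),
                    frac, time = time, event = event, subtype = subtype,
                    check.names = FALSE)
  list(table = tab,
       truth = list(archetype = archetype, archetype_centers = arch_centers,
                    ect_membership = glob$ect_membership, effect = effect))
}
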