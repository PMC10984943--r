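# Shared fixture builders; everything is generated in code at test time.

# Minimal hand-built section: explicit coordinates and abundances.
make_section <- function(ab, coords = NULL, section_id = "S01",
                         spot_diameter = 55) {
  ab <- as.matrix(ab)
  if (is.null(rownames(ab)))
    rownames(ab) <- sprintf("%s_spot%03d", section_id, seq_len(nrow(ab)))
  if (is.null(coords))
    coords <- hex_lattice_fixture(nrow(ab), pitch = 100)
  new_section(section_id = section_id, spot_ids = rownames(ab),
              coords = coords, spot_diameter = spot_diameter, abundance = ab)
}

hex_lattice_fixture <- function(n, pitch = 100) {
  ncol_ <- max(1L, ceiling(sqrt(n)))
  row <- rep(seq_len(ceiling(n / ncol_)) - 1L, each = ncol_)[seq_len(n)]
  col <- rep(seq_len(ncol_) - 1L, times = ceiling(n / ncol_))[seq_len(n)]
  cbind(x = col * pitch + (row %% 2L) * pitch / 2, y = row * pitch * sqrt(3) / 2)
}

# A hand-built cell map (bypasses placement) for distance tests.
make_cellmap <- function(types, x, y, section_id = "S01") {
  out <- data.frame(cell_type = types, x_um = x, y_um = y,
                    spot_id = sprintf("sp%03d", seq_along(types)),
                    section_id = section_id)
  class(out) <- c("ect_cellmap", "data.frame")
  out
}

# Small but structured simulation used by several suites.
small_sim <- function(seed = 11, n_sections = 3, spots = 300, d = 10,
                      niches = 3, blocks = 3, conc = 300, batch_sd = 0.2) {
  cfg <- sim_config(n_sections = n_sections, spots_per_section = spots,
                    n_cell_types = d, n_niches = niches,
                    niche_center_concentration = conc,
                    batch_shift_sd = batch_sd, n_ect_blocks = blocks,
                    seed = seed)
  list(cfg = cfg, sim = generate_sections(cfg))
}

truth_labels <- function(sim) unlist(unname(sim$truth$niche_labels))

# Independent centred-log-ratio helper for Aitchison-distance oracles.
clr_oracle <- function(p) log(p) - mean(log(p))
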