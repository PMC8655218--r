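#' Synthetic nanoprecipitation data with known ground truth
#'
#' Emulates the structure of a high-throughput methacrylate
#' nanoprecipitation screen — a battery of repeat units, several degrees
#' of polymerization per polymer, concentrations of 1–30 g/L, surfactant
#' on/off, each formulation prepared in triplicate and measured three
#' times — on top of an invented closed-form size law, so that every
#' downstream module can be validated against exact bookkeeping. The law
#' is not a physical nanoprecipitation model; it is chosen monotone in
#' concentration and chain length (echoing the qualitative shape of real
#' prediction surfaces) and depends on structure only through a
#' graph-computable descriptor, so a graph network can in principle learn
#' it.
#'
#' @name synthetic_data
NULL

#' The default methacrylate repeat-unit battery
#'
#' Ten carbon-side-chain methacrylates spanning methyl through benzyl and
#' isobornyl esters.
#'
#' @return Data frame with columns `name` and `smiles` (marked repeat-unit
#'   SMILES).
#' @export
default_monomer_battery <- function() {
  data.frame(
    name = c("methyl methacrylate", "ethyl methacrylate", "propyl methacrylate",
             "butyl methacrylate", "isobutyl methacrylate",
             "tert-butyl methacrylate", "hexyl methacrylate",
             "phenyl methacrylate", "benzyl methacrylate",
             "isobornyl methacrylate"),
    smiles = c("*CC(*)(C)C(=O)OC", "*CC(*)(C)C(=O)OCC", "*CC(*)(C)C(=O)OCCC",
               "*CC(*)(C)C(=O)OCCCC", "*CC(*)(C)C(=O)OCC(C)C",
               "*CC(*)(C)C(=O)OC(C)(C)C", "*CC(*)(C)C(=O)OCCCCCC",
               "*CC(*)(C)C(=O)Oc1ccccc1", "*CC(*)(C)C(=O)OCc1ccccc1",
               "*CC(*)(C)C(=O)OC1CC2CCC1(C)C2(C)C")
  )
}

#' Configuration of the synthetic generator
#'
#' All levels sit inside the parameter ranges of the emulated study: Dp in
#' \[53, 1013\], polymer concentration in \[1, 30\] g/L, surfactant either
#' absent or 0.0025 g/L.
#'
#' @param battery Repeat-unit battery (data frame `name`, `smiles`; >= 10
#'   units by default).
#' @param dp_levels Degrees of polymerization per unit.
#' @param conc_levels Polymer concentrations, g/L.
#' @param surfactant_levels Surfactant concentrations, g/L (0 = none).
#' @param coeffs Ground-truth coefficients, see [ground_truth_size()].
#' @param noise_sigma Log-scale standard deviation of the multiplicative
#'   lognormal measurement noise (DLS size errors scale with size;
#'   default 0.05).
#' @param outlier_rate Fraction of measurements planted as 3x replicate
#'   outliers.
#' @param invalid_rate Fraction planted as invalid rows (high
#'   polydispersity or missing size).
#' @param extreme_dp Optional list `list(unit = <name>, dp = <value>)`
#'   adding an extra, peripheral Dp level for one unit — the planted
#'   "hardly predictable" group for worst-group recovery tests.
#' @param seed Mandatory RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(battery = default_monomer_battery(),
                         dp_levels = c(60, 120, 220),
                         conc_levels = c(1, 3, 7.5, 15, 30),
                         surfactant_levels = c(0, 0.0025),
                         coeffs = list(a = 15, alpha = 0.4, beta = 1/3,
                                       gamma = 0.15, h_ref = 7, h_exp = 0.5),
                         noise_sigma = 0.05,
                         outlier_rate = 0.02,
                         invalid_rate = 0.02,
                         extreme_dp = NULL,
                         seed) {
  if (missing(seed)) abort("`seed` is mandatory", "polygcn_validation_error")
  if (any(dp_levels < 53 | dp_levels > 1013)) {
    abort("dp_levels must lie in [53, 1013]", "polygcn_validation_error")
  }
  if (any(conc_levels < 1 | conc_levels > 30)) {
    abort("conc_levels must lie in [1, 30] g/L", "polygcn_validation_error")
  }
  if (outlier_rate + invalid_rate > 1) {
    abort("outlier_rate + invalid_rate must not exceed 1", "polygcn_validation_error")
  }
  structure(list(battery = battery, dp_levels = dp_levels,
                 conc_levels = conc_levels, surfactant_levels = surfactant_levels,
                 coeffs = coeffs, noise_sigma = noise_sigma,
                 outlier_rate = outlier_rate, invalid_rate = invalid_rate,
                 extreme_dp = extreme_dp, seed = as.integer(seed)),
            class = "synth_config")
}

#' Closed-form ground-truth particle size
#'
#' \deqn{s = a \cdot Dp^{\alpha} \cdot c^{\beta} \cdot h(\mathrm{unit})
#'       \cdot (1 - \gamma \cdot [\mathrm{surfactant\ present}])}
#' with the structure descriptor \eqn{h = (k / h_{ref})^{h_{exp}}}, `k`
#' the heavy-atom count of the repeat unit. Monotone increasing in Dp and
#' concentration, decreasing with surfactant, larger for bulkier side
#' chains; defaults keep the whole default grid inside 10–1000 nm.
#'
#' @param unit Repeat unit or marked SMILES.
#' @param form List with `dp`, `conc`, `surfactant` (as in
#'   [predict_size()]).
#' @param coeffs Coefficient list (`a`, `alpha`, `beta`, `gamma`, `h_ref`,
#'   `h_exp`).
#' @return Ground-truth size, nm.
#' @export
ground_truth_size <- function(unit, form,
                              coeffs = synth_config(seed = 0)$coeffs) {
  unit <- as_repeat_unit(unit)
  check_scalar_number(form$dp, "dp", lower = 1e-9)
  h <- (unit$k / coeffs$h_ref)^coeffs$h_exp
  s <- coeffs$a * form$dp^coeffs$alpha * form$conc^coeffs$beta * h *
    (1 - coeffs$gamma * (form$surfactant > 0))
  if (!is.finite(s) || s <= 0) {
    abort("ground-truth coefficients produce a non-positive size", "polygcn_config_error")
  }
  s
}

# full factorial formulation grid (one row per formulation)
synth_grid <- function(cfg) {
  grid <- expand.grid(unit_idx = seq_len(nrow(cfg$battery)),
                      dp = cfg$dp_levels, conc = cfg$conc_levels,
                      surfactant = cfg$surfactant_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$unit_idx, grid$dp, grid$conc, grid$surfactant), ]
  if (!is.null(cfg$extreme_dp)) {
    u <- which(cfg$battery$name == cfg$extreme_dp$unit)
    if (length(u) != 1L) {
      abort(sprintf("extreme_dp unit '%s' not in battery", cfg$extreme_dp$unit),
            "polygcn_config_error")
    }
    extra <- expand.grid(unit_idx = u, dp = cfg$extreme_dp$dp,
                         conc = cfg$conc_levels, surfactant = cfg$surfactant_levels,
                         KEEP.OUT.ATTRS = FALSE)
    grid <- rbind(grid, extra)
  }
  grid$polymer <- cfg$battery$name[grid$unit_idx]
  grid$smiles <- cfg$battery$smiles[grid$unit_idx]
  rownames(grid) <- NULL
  grid
}

#' Generate a raw replicate measurement table with planted anomalies
#'
#' Every formulation of the factorial grid is "performed" three times and
#' each replicate "measured" three times. Measurements carry
#' multiplicative lognormal noise on the ground truth; a configured
#' fraction of rows is planted as 3x outliers, and another fraction as
#' invalid rows (half with polydispersity drawn above any sane threshold,
#' half with a missing size). Byte-identical output for a given seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `raw` (data frame in the schema of
#'   [filter_invalid()], plus a `row_id` column) and `planted` (data frame
#'   `row_id`, `type` in `outlier`, `invalid_pdi`, `invalid_missing`).
#' @export
generate_raw_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- synth_grid(cfg)
  units <- lapply(seq_len(nrow(cfg$battery)), function(i)
    parse_repeat_unit(cfg$battery$smiles[i], cfg$battery$name[i]))
  truth <- vapply(seq_len(nrow(grid)), function(r)
    ground_truth_size(units[[grid$unit_idx[r]]],
                      list(dp = grid$dp[r], conc = grid$conc[r],
                           surfactant = grid$surfactant[r]), cfg$coeffs),
    numeric(1))

  reps <- expand.grid(measurement = 1:3, replicate = 1:3,
                      row = seq_len(nrow(grid)), KEEP.OUT.ATTRS = FALSE)
  reps <- reps[order(reps$row, reps$replicate, reps$measurement), ]
  n <- nrow(reps)
  raw <- data.frame(
    row_id = seq_len(n),
    polymer = grid$polymer[reps$row], smiles = grid$smiles[reps$row],
    dp = grid$dp[reps$row], conc = grid$conc[reps$row],
    surfactant = grid$surfactant[reps$row],
    replicate = reps$replicate, measurement = reps$measurement
  )
  true_size <- truth[reps$row]

  with_seed(cfg$seed, {
    size <- true_size * exp(stats::rnorm(n, 0, cfg$noise_sigma))
    pdi <- stats::runif(n, 0.05, 0.2)

    n_invalid <- round(cfg$invalid_rate * n)
    n_outlier <- round(cfg$outlier_rate * n)
    planted_rows <- sample.int(n, n_invalid + n_outlier)
    invalid_rows <- planted_rows[seq_len(n_invalid)]
    outlier_rows <- setdiff(planted_rows, invalid_rows)

    # invalid: half high dispersity, half missing size
    half <- invalid_rows[seq_len(floor(n_invalid / 2))]
    pdi[half] <- stats::runif(length(half), 0.5, 1.0)
    miss <- setdiff(invalid_rows, half)
    size[miss] <- NA_real_
    size[outlier_rows] <- size[outlier_rows] * 3

    raw$size_nm <- size
    raw$pdi <- pdi
    planted <- rbind(
      if (length(half)) data.frame(row_id = sort(half), type = "invalid_pdi"),
      if (length(miss)) data.frame(row_id = sort(miss), type = "invalid_missing"),
      if (length(outlier_rows)) data.frame(row_id = sort(outlier_rows), type = "outlier")
    )
    if (is.null(planted)) planted <- data.frame(row_id = integer(0), type = character(0))
    list(raw = raw, planted = planted)
  })
}

#' Generate a clean modeling dataset from the ground-truth law
#'
#' The factorial grid with nine noisy measurements per formulation, no
#' planted anomalies; optionally subsampled to `n` records.
#'
#' @param cfg A [synth_config()].
#' @param n Optional record count to subsample to (seeded).
#' @return A [formulation_dataset()].
#' @export
generate_clean_dataset <- function(cfg, n = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- synth_grid(cfg)
  units <- lapply(seq_len(nrow(cfg$battery)), function(i)
    parse_repeat_unit(cfg$battery$smiles[i], cfg$battery$name[i]))
  truth <- vapply(seq_len(nrow(grid)), function(r)
    ground_truth_size(units[[grid$unit_idx[r]]],
                      list(dp = grid$dp[r], conc = grid$conc[r],
                           surfactant = grid$surfactant[r]), cfg$coeffs),
    numeric(1))
  idx <- rep(seq_len(nrow(grid)), each = 9L)
  df <- data.frame(polymer = grid$polymer[idx], smiles = grid$smiles[idx],
                   dp = grid$dp[idx], conc = grid$conc[idx],
                   surfactant = grid$surfactant[idx])
  with_seed(cfg$seed, {
    df$size_nm <- truth[idx] * exp(stats::rnorm(nrow(df), 0, cfg$noise_sigma))
    if (!is.null(n)) {
      if (n > nrow(df)) abort("requested more records than the grid provides",
                              "polygcn_validation_error")
      df <- df[sort(sample.int(nrow(df), n)), , drop = FALSE]
    }
    formulation_dataset(df)
  })
}

#' Write the generator bookkeeping side-car CSV
#'
#' @param planted Bookkeeping data frame from [generate_raw_table()].
#' @param path Output path.
#' @export
write_bookkeeping_csv <- function(planted, path) {
  utils::write.csv(planted, path, row.names = FALSE)
  invisible(path)
}
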