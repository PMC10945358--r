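#' Describe a paired natural/cultivated sampling design
#'
#' A crossed design of sites x land-use types x field plots x sampling
#' depths. The default reproduces a 3-site, 2-type, 4-plot, 2-depth layout
#' (48 composite samples) typical of paired peatland cultivation studies.
#'
#' @param n_sites Number of sites.
#' @param site_labels Site labels; recycled/truncated to `n_sites`.
#' @param n_types Number of land-use types (2: natural, cultivated).
#' @param type_labels Land-use labels.
#' @param n_plots_per_type Independent field plots within each site x type.
#' @param n_depths Number of sampling depths.
#' @param depth_labels Depth interval labels.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_sites = 3,
                        site_labels = c("JC", "SP", "YSJ"),
                        n_types = 2,
                        type_labels = c("natural", "cultivated"),
                        n_plots_per_type = 4,
                        n_depths = 2,
                        depth_labels = c("0-15 cm", "15-30 cm")) {
  counts <- c(n_sites = n_sites, n_types = n_types,
              n_plots_per_type = n_plots_per_type, n_depths = n_depths)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all design counts must be integers >= 1", call. = FALSE)
  }
  if (length(site_labels) < n_sites) {
    site_labels <- paste0("S", seq_len(n_sites))
  }
  if (length(type_labels) < n_types) {
    type_labels <- paste0("type", seq_len(n_types))
  }
  if (length(depth_labels) < n_depths) {
    depth_labels <- paste0("depth", seq_len(n_depths))
  }
  structure(list(n_sites = n_sites,
                 site_labels = site_labels[seq_len(n_sites)],
                 n_types = n_types,
                 type_labels = type_labels[seq_len(n_types)],
                 n_plots_per_type = n_plots_per_type,
                 n_depths = n_depths,
                 depth_labels = depth_labels[seq_len(n_depths)]),
            class = "design_spec")
}

#' Expand a design into a sample metadata table
#'
#' Enumerates every site x land-use x plot x depth combination as one
#' composite sample record; the default design yields 48 samples.
#'
#' @param spec A [design_spec()].
#' @return A data.frame with columns `sample_id`, `site`, `land_use`,
#'   `plot`, `depth`.
#' @export
generate_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  grid <- expand.grid(
    depth = spec$depth_labels,
    plot = paste0("P", seq_len(spec$n_plots_per_type)),
    land_use = spec$type_labels,
    site = spec$site_labels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("site", "land_use", "plot", "depth")]
  depth_code <- paste0("D", match(grid$depth, spec$depth_labels))
  grid <- data.frame(
    sample_id = paste(grid$site, grid$land_use, grid$plot, depth_code,
                      sep = "_"),
    grid, stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(grid$sample_id))
  rownames(grid) <- NULL
  grid
}

#' Configure the synthetic community generator
#'
#' Parameters for a logistic-normal-multinomial community simulation with
#' planted correlation modules and planted trait-module associations.
#' Latent per-sample log-abundances are multivariate normal with an
#' equicorrelated block per module (`within_correlation` inside a block,
#' zero elsewhere); counts are multinomial draws from the softmax of the
#' latents, so compositional distortion matches the assumption SparCC is
#' designed to undo.
#'
#' @param n_taxa Number of taxa.
#' @param sequencing_depth Reads per sample (every generated sample sums to
#'   exactly this). At least 10x `n_taxa` is recommended.
#' @param module_spec List of planted modules, each `list(size =, rho =)`
#'   with `rho` the within-module latent correlation in `[0, 1]`. Module
#'   sizes must sum to at most `n_taxa`; leftover taxa are uncorrelated
#'   background.
#' @param trait_links Data frame with columns `trait`, `module`,
#'   `target_r`: each listed trait is tied to the named planted module so
#'   that its expected Pearson correlation with the module's mean
#'   standardized latent signal equals `target_r` (|target_r| < 1).
#' @param traits Character vector of all trait columns to emit; traits not
#'   in `trait_links` are independent noise.
#' @param trait_scales Named list mapping trait -> `c(mean, sd)` used to put
#'   traits on interpretable measurement scales (a positive affine map, so
#'   planted correlations are untouched). Unlisted traits get mean 0, sd 1.
#' @param noise_sd Standard deviation of the latent log-abundance
#'   fluctuation around each taxon's baseline.
#' @param archaea_fraction Fraction of background taxa labelled with an
#'   archaeal lineage, to exercise the archaea filter.
#' @param seed Integer seed; identical configurations generate identical
#'   tables.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_taxa = 300,
                         sequencing_depth = 5000,
                         module_spec = list(),
                         trait_links = NULL,
                         traits = c("CMR", "phenolics", "carbohydrates",
                                    "DOC", "FTIR_1630_1030", "SOC"),
                         trait_scales = list(),
                         noise_sd = 1,
                         archaea_fraction = 0.05,
                         seed = 1) {
  if (n_taxa < 1) stop("`n_taxa` must be >= 1", call. = FALSE)
  if (sequencing_depth < 1) {
    stop("`sequencing_depth` must be >= 1", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  sizes <- vapply(module_spec, function(m) m$size, numeric(1))
  rhos <- vapply(module_spec, function(m) m$rho, numeric(1))
  if (sum(sizes) > n_taxa) {
    stop("module sizes sum to more than `n_taxa`", call. = FALSE)
  }
  for (k in seq_along(module_spec)) {
    # equicorrelated block is positive definite iff rho > -1/(size - 1)
    lower <- if (sizes[k] > 1) -1 / (sizes[k] - 1) else -1
    if (rhos[k] > 1 || rhos[k] <= lower) {
      stop("module ", k, ": within_correlation ", rhos[k],
           " makes the implied correlation matrix non-positive-definite ",
           "(must be in (", signif(lower, 3), ", 1])", call. = FALSE)
    }
  }
  if (!is.null(trait_links)) {
    stopifnot(all(c("trait", "module", "target_r") %in% names(trait_links)))
    if (any(abs(trait_links$target_r) >= 1)) {
      stop("|target_r| must be < 1", call. = FALSE)
    }
    if (any(trait_links$module < 1 | trait_links$module > length(module_spec))) {
      stop("trait_links reference module indices outside module_spec",
           call. = FALSE)
    }
  }
  structure(list(n_taxa = n_taxa, sequencing_depth = sequencing_depth,
                 module_spec = module_spec, trait_links = trait_links,
                 traits = traits, trait_scales = trait_scales,
                 noise_sd = noise_sd, archaea_fraction = archaea_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate an OTU count table with planted correlation modules
#'
#' Draws latent log-abundances per sample from a block-structured
#' multivariate normal (taxon baselines from N(0,1); equicorrelated blocks
#' per planted module) and converts them to counts by multinomial sampling
#' of the softmax-transformed latents, so every sample sums exactly to
#' `sequencing_depth`. A configurable fraction of background taxa carries
#' an archaeal lineage. The returned table additionally records the latent
#' matrix (`$latent`) and the planted module assignment
#' (`$planted_module`, 0 = background) so planted structure can be scored
#' downstream.
#'
#' @param metadata Sample metadata from [generate_design()].
#' @param config A [synth_config()].
#' @return A [otu_table()] with extra fields `latent` and `planted_module`.
#' @export
generate_counts <- function(metadata, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- nrow(metadata)
  p <- config$n_taxa
  set.seed(config$seed)
  taxa <- sprintf("OTU%04d", seq_len(p))
  sizes <- vapply(config$module_spec, function(m) m$size, numeric(1))
  planted <- rep(0L, p)
  if (length(sizes)) {
    planted[seq_len(sum(sizes))] <- rep(seq_along(sizes), times = sizes)
  }
  baseline <- stats::rnorm(p)

  latent <- matrix(0, nrow = p, ncol = n, dimnames = list(taxa, metadata$sample_id))
  for (j in seq_len(n)) {
    z <- stats::rnorm(p)
    for (k in seq_along(config$module_spec)) {
      idx <- which(planted == k)
      rho <- config$module_spec[[k]]$rho
      shared <- stats::rnorm(1)
      z[idx] <- sqrt(rho) * shared + sqrt(1 - rho) * z[idx]
    }
    latent[, j] <- baseline + config$noise_sd * z
  }

  counts <- matrix(0L, nrow = p, ncol = n, dimnames = dimnames(latent))
  for (j in seq_len(n)) {
    pr <- exp(latent[, j] - max(latent[, j]))
    pr <- pr / sum(pr)
    counts[, j] <- stats::rmultinom(1, size = config$sequencing_depth, prob = pr)
  }

  # archaeal lineages only on background taxa so planted modules survive
  # the archaea filter intact
  background <- which(planted == 0L)
  n_arch <- min(length(background),
                round(config$archaea_fraction * length(background)))
  arch_idx <- background[seq_len(n_arch)]
  lineage <- rep("d__Bacteria;p__Proteobacteria;c__;o__;f__;g__;s__", p)
  lineage[arch_idx] <- "d__Archaea;p__Crenarchaeota;c__;o__;f__;g__;s__"
  taxonomy <- setNames(lineage, taxa)

  tab <- otu_table(counts, taxonomy,
                   provenance = sprintf(
                     "synthetic community: %d taxa x %d samples, depth %d, %d planted module(s), seed %d",
                     p, n, config$sequencing_depth,
                     length(config$module_spec), config$seed))
  tab$latent <- latent
  tab$planted_module <- setNames(planted, taxa)
  tab
}

#' Closed-form noise scale for a target trait-signal correlation
#'
#' For a trait built as signal plus independent Gaussian noise, the noise
#' variance giving expected Pearson correlation `target_r` with the signal
#' is `var_signal * (1 / target_r^2 - 1)`; this returns its square root.
#'
#' @param target_r Target correlation, 0 < |target_r| < 1.
#' @param var_signal Variance of the signal (default 1, a standardized
#'   signal).
#' @return The noise standard deviation.
#' @export
solve_noise_sd <- function(target_r, var_signal = 1) {
  if (any(target_r == 0) || any(abs(target_r) >= 1)) {
    stop("`target_r` must satisfy 0 < |target_r| < 1", call. = FALSE)
  }
  sqrt(var_signal * (1 / target_r^2 - 1))
}

#' Simulate soil traits with planted trait-module associations
#'
#' Each trait listed in the configuration's `trait_links` is built as the
#' target module's mean standardized latent signal plus independent
#' Gaussian noise whose variance is solved in closed form
#' ([solve_noise_sd()]) so the expected Pearson correlation between trait
#' and module signal equals `target_r`; the sign of `target_r` sets the
#' direction. Unlinked traits are independent noise. All traits are then
#' mapped onto their measurement scales by the positive affine transform in
#' `trait_scales`, which leaves every planted correlation untouched.
#'
#' @param metadata Sample metadata from [generate_design()].
#' @param counts The table produced by [generate_counts()] under the same
#'   configuration (its latent matrix defines the module signals).
#' @param config A [synth_config()].
#' @return A data.frame with `sample_id` and one numeric column per trait.
#' @export
generate_traits <- function(metadata, counts, config) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(counts$latent) || is.null(counts$planted_module)) {
    stop("`counts` must come from generate_counts() (latent signals needed)",
         call. = FALSE)
  }
  n <- nrow(metadata)
  # separate stream from generate_counts so traits are reproducible from
  # (counts, config) alone
  set.seed(config$seed + 1L)
  zlat <- t(scale(t(counts$latent)))  # standardize each taxon across samples

  module_signal <- function(k) {
    idx <- which(counts$planted_module == k)
    if (!length(idx)) {
      stop("trait link references empty module ", k, call. = FALSE)
    }
    g <- colMeans(zlat[idx, , drop = FALSE])
    as.numeric(scale(g))
  }

  out <- data.frame(sample_id = metadata$sample_id, stringsAsFactors = FALSE)
  links <- config$trait_links
  for (trait in config$traits) {
    hit <- if (!is.null(links)) which(links$trait == trait) else integer()
    if (length(hit) == 1L) {
      r <- links$target_r[hit]
      if (r == 0) {
        val <- stats::rnorm(n)
      } else {
        g <- module_signal(links$module[hit])
        raw <- sign(r) * g + solve_noise_sd(r) * stats::rnorm(n)
        # raw has variance 1/r^2; rescale to unit variance in expectation
        val <- abs(r) * raw
      }
    } else {
      val <- stats::rnorm(n)
    }
    sc <- config$trait_scales[[trait]]
    if (is.null(sc)) sc <- c(0, 1)
    if (sc[2] <= 0) stop("trait scale sd must be > 0", call. = FALSE)
    out[[trait]] <- sc[1] + sc[2] * val
  }
  out
}

#' Default synthetic scenarios for natural and cultivated peatlands
#'
#' Two ready-made configurations mirroring the study conditions the
#' generator emulates. Both use the 48-sample paired design (24 samples per
#' land use once split by group) and plant one trait-anchored module plus
#' additional community modules. CMR is tied to module 1 with a strong
#' link (`cmr_link`); the trait(s) measured against CMR are tied to the
#' same module with link strengths chosen so the implied trait-trait
#' correlation (the product of the two link strengths, since the trait
#' noises are independent) equals the scenario's field value:
#'
#' * natural: carbohydrates-CMR r = 0.60 (labile C fuels mineralization);
#'   phenolics unlinked (no phenolic inhibition detectable).
#' * cultivated: phenolics-CMR r = -0.58 and carbohydrates-CMR r = -0.66
#'   (phenolic inhibition exposed once labile C is depleted).
#'
#' @param seed Integer seed.
#' @param n_taxa,sequencing_depth Community size and per-sample depth.
#' @return A [synth_config()].
#' @name scenarios
NULL

scenario_base <- function(seed, n_taxa, sequencing_depth, trait_links,
                          trait_scales) {
  # module sizes track community size (25/25/20 taxa at the default 300)
  sizes <- pmax(4, round(c(25, 25, 20) * n_taxa / 300))
  synth_config(
    n_taxa = n_taxa,
    sequencing_depth = sequencing_depth,
    module_spec = list(list(size = sizes[1], rho = 0.85),
                       list(size = sizes[2], rho = 0.85),
                       list(size = sizes[3], rho = 0.7)),
    trait_links = trait_links,
    trait_scales = trait_scales,
    seed = seed
  )
}

#' @rdname scenarios
#' @export
scenario_natural <- function(seed = 1, n_taxa = 300, sequencing_depth = 5000) {
  cmr_link <- 0.9
  carb_cmr <- 0.60   # field value: carbohydrates vs CMR, natural peatland
  scenario_base(
    seed, n_taxa, sequencing_depth,
    trait_links = data.frame(
      trait = c("CMR", "carbohydrates"),
      module = c(1L, 1L),
      target_r = c(cmr_link, carb_cmr / cmr_link),
      stringsAsFactors = FALSE
    ),
    trait_scales = list(
      CMR = c(5, 1.5),             # mg C / kg SOC / d
      phenolics = c(6, 1.2),       # mg GAE / L
      carbohydrates = c(40, 8),    # % of DOC
      DOC = c(350, 60),            # mg C / L extract
      FTIR_1630_1030 = c(1.6, 0.2),
      SOC = c(280, 40)             # g C / kg soil
    )
  )
}

#' @rdname scenarios
#' @export
scenario_cultivated <- function(seed = 1, n_taxa = 300,
                                sequencing_depth = 5000) {
  cmr_link <- 0.9
  phen_cmr <- -0.58  # field value: phenolics vs CMR, cultivated peatland
  carb_cmr <- -0.66  # field value: carbohydrates vs CMR, cultivated peatland
  scenario_base(
    seed, n_taxa, sequencing_depth,
    trait_links = data.frame(
      trait = c("CMR", "phenolics", "carbohydrates"),
      module = c(1L, 1L, 1L),
      target_r = c(cmr_link, phen_cmr / cmr_link, carb_cmr / cmr_link),
      stringsAsFactors = FALSE
    ),
    trait_scales = list(
      CMR = c(15, 4),
      phenolics = c(3, 0.8),
      carbohydrates = c(18, 5),
      DOC = c(180, 40),
      FTIR_1630_1030 = c(1.1, 0.15),
      SOC = c(160, 30)
    )
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: expands the design, simulates counts and traits
#' under one configuration, optionally restricted to one land use (the
#' per-group situation in which networks are built).
#'
#' @param config A [synth_config()], e.g. [scenario_natural()].
#' @param spec A [design_spec()].
#' @param land_use Optional `"natural"` or `"cultivated"` to keep only one
#'   group's samples.
#' @return A list with `metadata`, `counts` and `traits`.
#' @export
simulate_study <- function(config, spec = design_spec(), land_use = NULL) {
  metadata <- generate_design(spec)
  if (!is.null(land_use)) {
    metadata <- metadata[metadata$land_use == land_use, , drop = FALSE]
    rownames(metadata) <- NULL
  }
  counts <- generate_counts(metadata, config)
  traits <- generate_traits(metadata, counts, config)
  list(metadata = metadata, counts = counts, traits = traits)
}
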