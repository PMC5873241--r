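# Synthetic populations of provisioning predators. The generator emulates
# the sampling frame of a nest-cell study: ~30 individuals, 1-3 provisioned
# cells each, 5-25 prey items per cell, a population diet dominated by one
# resource, coexisting specialists and generalists, optionally nested or
# modular diet structure, and prey sizes with taxon, individual and residual
# components.

DEFAULT_RESOURCES <- c(
  Nephilidae = 0.73, Araneidae = 0.09, Salticidae = 0.08,
  Thomisidae = 0.05, Oxyopidae = 0.03, Anyphaenidae = 0.02
)

DEFAULT_GUILD_MAP <- c(
  Nephilidae = "orb_weaver", Araneidae = "orb_weaver",
  Salticidae = "active_hunter", Anyphaenidae = "active_hunter",
  Thomisidae = "ambush_hunter", Oxyopidae = "ambush_hunter"
)

#' Configuration for the synthetic-population generator
#'
#' @param n_individuals Number of individuals (nests); default 30.
#' @param resources Named numeric vector: the population availability q0 of
#'   each resource category (normalized to sum to 1). The default puts 73%
#'   of availability on one dominant taxon over 6 spider families.
#' @param concentration Dirichlet concentration alpha (> 0) controlling diet
#'   heterogeneity under `structure = "dirichlet"`: individual diets are
#'   drawn from Dirichlet(alpha * q0 * K). Small alpha (~0.1) yields
#'   specialists, large alpha (~10+) near-identical generalists.
#' @param structure Diet architecture: `"dirichlet"` (heterogeneity around
#'   q0), `"nested"` (individual i forages on the top r_i resources of q0,
#'   r_i uniform on 1..K, so specialist diets are subsets of generalist
#'   diets), or `"modular"` (individuals partitioned into `n_groups` groups,
#'   each confined to a disjoint block of resources).
#' @param n_groups Number of groups for `structure = "modular"`; must not
#'   exceed the number of resources.
#' @param cells_per_individual Integer range `c(min, max)` of provisioned
#'   cells per individual; default 1-3.
#' @param items_per_cell Integer range of prey items per cell; default 5-25.
#' @param drift In \[0, 1\]: each cell's diet is
#'   `(1 - drift) * p_i + drift * fresh redraw`, so 0 means perfectly
#'   consistent diets across cells and 1 an independent redraw per cell.
#' @param size_model List with `mu` (per-resource mean body length, mm;
#'   default evenly spaced over 4-12 mm), `sigma_b` (between-individual SD,
#'   mm; default 1), `sigma_w` (within-individual residual SD, mm; default
#'   1.5) and `carapace_scale` (carapace width as a fraction of the body
#'   length scale; default 0.25). Item body length is
#'   `mu_k + delta_i + eps` with `delta_i ~ N(0, sigma_b)` per individual
#'   and `eps ~ N(0, sigma_w)` per item; carapace width uses the same
#'   components scaled by `carapace_scale` with its own residual. Sizes are
#'   truncated at the 0.1 mm floor (the truncation count is reported as an
#'   attribute of the generated records).
#' @param guild_map Named character vector mapping resource labels to
#'   ecological guilds; defaults to a 3-guild map for the default resources,
#'   otherwise each resource is its own guild.
#' @param seed Integer seed; all draws flow from one generator seeded once.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_individuals = 30L,
                             resources = DEFAULT_RESOURCES,
                             concentration = 1,
                             structure = c("dirichlet", "nested", "modular"),
                             n_groups = 3L,
                             cells_per_individual = c(1L, 3L),
                             items_per_cell = c(5L, 25L),
                             drift = 0,
                             size_model = list(),
                             guild_map = NULL,
                             seed = NULL) {
  structure_ <- match.arg(structure)
  if (is.null(names(resources))) {
    names(resources) <- paste0("R", seq_along(resources))
  }
  if (any(resources <= 0)) stop_ds("resource availabilities must be > 0")
  resources <- resources / sum(resources)
  if (concentration <= 0) stop_ds("concentration must be > 0")
  if (length(cells_per_individual) == 1L) {
    cells_per_individual <- rep(cells_per_individual, 2L)
  }
  if (length(items_per_cell) == 1L) items_per_cell <- rep(items_per_cell, 2L)
  if (cells_per_individual[1] > cells_per_individual[2] ||
      items_per_cell[1] > items_per_cell[2] ||
      cells_per_individual[1] < 1L || items_per_cell[1] < 1L) {
    stop_ds("cells_per_individual and items_per_cell must be non-empty ",
            "positive ranges")
  }
  if (drift < 0 || drift > 1) stop_ds("drift must be in [0, 1]")
  if (structure_ == "modular" && n_groups > length(resources)) {
    stop_ds("modular structure needs n_groups <= number of resources")
  }
  k <- length(resources)
  sm <- utils::modifyList(
    list(mu = seq(4, 12, length.out = k), sigma_b = 1, sigma_w = 1.5,
         carapace_scale = 0.25),
    size_model
  )
  if (length(sm$mu) != k) stop_ds("size_model$mu needs one mean per resource")
  if (sm$sigma_b < 0 || sm$sigma_w < 0) stop_ds("size SDs must be >= 0")
  if (is.null(guild_map)) {
    guild_map <- if (identical(names(resources), names(DEFAULT_RESOURCES))) {
      DEFAULT_GUILD_MAP
    } else {
      stats::setNames(names(resources), names(resources))
    }
  }
  if (!all(names(resources) %in% names(guild_map))) {
    stop_ds("guild_map must cover every resource")
  }
  structure(
    list(n_individuals = as.integer(n_individuals), resources = resources,
         concentration = concentration, structure = structure_,
         n_groups = as.integer(n_groups),
         cells_per_individual = as.integer(cells_per_individual),
         items_per_cell = as.integer(items_per_cell), drift = drift,
         size_model = sm, guild_map = guild_map, seed = seed),
    class = "synthetic_config"
  )
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [synthetic_config()]; `resources` and `guild_map` may be
#'   given as named maps.
#' @return A `synthetic_config`.
#' @export
synthetic_config_from_file <- function(path) {
  if (!file.exists(path)) stop_ds("no such file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (field in c("resources", "guild_map")) {
    if (!is.null(raw[[field]])) raw[[field]] <- unlist(raw[[field]])
  }
  do.call(synthetic_config, raw)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) {          # numerically possible at tiny alpha
    g[sample.int(length(alpha), 1L)] <- 1
  }
  g / sum(g)
}

# one draw of a base diet under the configured architecture
draw_diet <- function(config, group = NULL) {
  q0 <- config$resources
  k <- length(q0)
  switch(config$structure,
    dirichlet = rdirichlet1(config$concentration * q0 * k),
    nested = {
      r <- sample.int(k, 1L)
      top <- order(q0, decreasing = TRUE)[seq_len(r)]
      p <- numeric(k)
      p[top] <- q0[top] / sum(q0[top])
      p
    },
    modular = {
      blocks <- split(seq_len(k), cut(seq_len(k), config$n_groups,
                                      labels = FALSE))
      p <- numeric(k)
      b <- blocks[[group]]
      p[b] <- q0[b] / sum(q0[b])
      p
    }
  )
}

#' Generate a synthetic population of prey records
#'
#' @param config A [synthetic_config()].
#' @return A `prey_records` data frame (one row per prey item) with
#'   attributes `base_diets` (the individuals-by-resources matrix of latent
#'   diet proportions) and `n_truncated` (how many sizes hit the 0.1 mm
#'   floor). Deterministic given `config$seed`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  q0 <- config$resources
  k <- length(q0)
  res_names <- names(q0)
  sm <- config$size_model
  n_trunc <- 0L
  with_seed(config$seed, {
    groups <- if (config$structure == "modular") {
      rep_len(seq_len(config$n_groups), config$n_individuals)
    } else {
      rep(NA_integer_, config$n_individuals)
    }
    rows <- vector("list", config$n_individuals)
    base_diets <- matrix(0, config$n_individuals, k,
                         dimnames = list(NULL, res_names))
    for (i in seq_len(config$n_individuals)) {
      ind_id <- sprintf("W%02d", i)
      p_i <- draw_diet(config, groups[i])
      base_diets[i, ] <- p_i
      delta_i <- stats::rnorm(1L, 0, sm$sigma_b)
      n_cells <- sample(config$cells_per_individual[1]:
                        config$cells_per_individual[2], 1L)
      cell_rows <- vector("list", n_cells)
      for (cc in seq_len(n_cells)) {
        p_cell <- (1 - config$drift) * p_i +
          config$drift * draw_diet(config, groups[i])
        n_items <- sample(config$items_per_cell[1]:
                          config$items_per_cell[2], 1L)
        taxa <- sample.int(k, n_items, replace = TRUE, prob = p_cell)
        bl <- sm$mu[taxa] + delta_i + stats::rnorm(n_items, 0, sm$sigma_w)
        cw <- (sm$mu[taxa] + delta_i) * sm$carapace_scale +
          stats::rnorm(n_items, 0, sm$sigma_w * sm$carapace_scale)
        n_trunc <- n_trunc + sum(bl < 0.1) + sum(cw < 0.1)
        cell_rows[[cc]] <- data.frame(
          individual_id = ind_id,
          cell_id = sprintf("c%d", cc),
          family = res_names[taxa],
          genus = paste0(res_names[taxa], "_g1"),
          guild = unname(config$guild_map[res_names[taxa]]),
          body_length_mm = pmax(bl, 0.1),
          carapace_width_mm = pmax(cw, 0.1),
          genus_unidentifiable = FALSE,
          size_damaged = FALSE,
          stringsAsFactors = FALSE
        )
      }
      rows[[i]] <- do.call(rbind, cell_rows)
    }
    rownames(base_diets) <- sprintf("W%02d", seq_len(config$n_individuals))
    out <- prey_records(do.call(rbind, rows))
    attr(out, "base_diets") <- base_diets
    attr(out, "n_truncated") <- n_trunc
    out
  })
}

#' Summarize a population of prey records
#'
#' @param records A `prey_records` data frame.
#' @param level Classification level used for resource proportions
#'   (default `"family"`).
#' @return A data frame with one row per individual (`individual_id`,
#'   `n_cells`, `n_items`, `min_items_per_cell`, `max_items_per_cell`,
#'   `top_resource`, `top_prop`), plus attributes `population_top_resource`
#'   and `population_top_prop` (the dominance of the commonest resource in
#'   the pooled diet).
#' @export
describe_population <- function(records, level = "family") {
  records <- prey_records(records)
  if (nrow(records) == 0L) stop_ds("no records")
  by_ind <- split(records, first_appearance_factor(records$individual_id))
  summ <- do.call(rbind, lapply(by_ind, function(r) {
    per_cell <- table(r$cell_id)
    tab <- sort(table(r[[level]]), decreasing = TRUE)
    data.frame(
      individual_id = r$individual_id[1],
      n_cells = length(per_cell),
      n_items = nrow(r),
      min_items_per_cell = min(per_cell),
      max_items_per_cell = max(per_cell),
      top_resource = names(tab)[1],
      top_prop = as.numeric(tab[1]) / nrow(r),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  pop <- sort(table(records[[level]]), decreasing = TRUE)
  attr(summ, "population_top_resource") <- names(pop)[1]
  attr(summ, "population_top_prop") <- as.numeric(pop[1]) / sum(pop)
  summ
}
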