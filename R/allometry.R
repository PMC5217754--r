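#' Per-tree aboveground carbon stock from a pantropical allometry
#'
#' Computes the aboveground carbon stock (ACS, Mg C) of a single tree from its
#' diameter at breast height, wood density and the local climatic stress index
#' E, using the diameter--wood-density pantropical biomass allometry
#' \deqn{AGB = \exp(-1.803 - 0.976 E + 0.976 \ln WD + 2.673 \ln DBH -
#'   0.0299 [\ln DBH]^2)}
#' with AGB in kg. Biomass is assumed to be 50\% carbon and the result is
#' returned in Mg C per tree.
#'
#' @param dbh diameter at breast height in cm (> 0). Vectorised.
#' @param wd wood specific gravity in g cm^-3 (> 0). Recycled against `dbh`.
#' @param E dimensionless synthetic climatic (water-stress) index.
#' @param carbon_fraction fraction of biomass that is carbon; default 0.5.
#'
#' @return numeric vector of per-tree carbon stocks in Mg C.
#' @examples
#' tree_acs(30, 0.6, E = 0)   # about 0.314 Mg C
#' @export
tree_acs <- function(dbh, wd, E = 0, carbon_fraction = 0.5) {
  if (any(!is.finite(dbh)) || any(dbh <= 0))
    stop("'dbh' must be positive and finite")
  if (any(!is.finite(wd)) || any(wd <= 0))
    stop("'wd' must be positive and finite")
  ld <- log(dbh)
  agb_kg <- exp(-1.803 - 0.976 * E + 0.976 * log(wd) + 2.673 * ld -
                  0.0299 * ld^2)
  agb_kg * carbon_fraction / 1000
}

#' Build a wood-density lookup table with genus and site fallbacks
#'
#' Assembles the three-level lookup used to assign a wood density to every
#' tree: exact species values, genus averages, and a per-site average computed
#' over the identified trees of that site. Genus averages that are not supplied
#' are derived as the mean of the species-level entries of that genus.
#'
#' @param density data.frame with columns `level` (`"species"` or `"genus"`),
#'   `name`, and `wd` (g cm^-3).
#' @param site_wd named numeric vector of site-average wood densities, one
#'   entry per site id. May be omitted and supplied later via
#'   [site_mean_density()].
#'
#' @return an object of class `wd_table`: a list with elements `species`,
#'   `genus` (named numeric vectors) and `site` (named numeric vector).
#' @seealso [assign_wood_density()]
#' @export
wood_density_table <- function(density, site_wd = numeric()) {
  stopifnot(is.data.frame(density),
            all(c("level", "name", "wd") %in% names(density)))
  if (any(density$wd <= 0 | density$wd >= 1.5))
    stop("wood densities must lie in (0, 1.5) g cm^-3")
  sp <- density[density$level == "species", ]
  gn <- density[density$level == "genus", ]
  species <- stats::setNames(sp$wd, sp$name)
  genus <- stats::setNames(gn$wd, gn$name)
  # derive missing genus averages from species entries ("Genus species" names)
  sp_genus <- vapply(strsplit(names(species), "[ _]"), `[`, "", 1)
  for (g in setdiff(unique(sp_genus), names(genus))) {
    genus[g] <- mean(species[sp_genus == g])
  }
  structure(list(species = species, genus = genus, site = site_wd),
            class = "wd_table")
}

#' Read a wood-density table from CSV
#'
#' The file must have columns `level` (species/genus), `name` and `wd`.
#'
#' @param path path to a CSV file.
#' @inheritParams wood_density_table
#' @return a `wd_table` object.
#' @export
read_wood_density <- function(path, site_wd = numeric()) {
  wood_density_table(utils::read.csv(path, stringsAsFactors = FALSE), site_wd)
}

#' Site-average wood density from identified trees
#'
#' Computes, for one site, the average wood density over trees that received a
#' species- or genus-level density, and stores it in the table's site slot.
#' This is the terminal fallback for unidentified trees.
#'
#' @param table a `wd_table`.
#' @param trees inventory data.frame for the site (columns `taxon_species`,
#'   `taxon_genus`; `NA` for unidentified trees).
#' @param site_id site identifier to store the average under.
#' @return the updated `wd_table`.
#' @export
site_mean_density <- function(table, trees, site_id) {
  stopifnot(inherits(table, "wd_table"))
  wd <- rep(NA_real_, nrow(trees))
  sp <- as.character(trees$taxon_species)
  gn <- as.character(trees$taxon_genus)
  hit_sp <- !is.na(sp) & sp %in% names(table$species)
  wd[hit_sp] <- table$species[sp[hit_sp]]
  hit_gn <- is.na(wd) & !is.na(gn) & gn %in% names(table$genus)
  wd[hit_gn] <- table$genus[gn[hit_gn]]
  if (all(is.na(wd)))
    stop("no identified trees at site '", site_id,
         "': cannot form a site-average wood density")
  table$site[as.character(site_id)] <- mean(wd, na.rm = TRUE)
  table
}

#' Assign a wood density to one tree by the species/genus/site protocol
#'
#' Implements the standard fallback chain: (i) a tree identified to species
#' level takes the species value; (ii) otherwise, a tree identified to genus
#' level takes the genus average; (iii) otherwise the site average. The chain
#' is total: every tree receives a density or an explicit configuration error
#' is raised when the site average is missing.
#'
#' @param tree one-row data.frame (or list) with `taxon_species` and
#'   `taxon_genus` fields, `NA` when unidentified.
#' @param table a `wd_table`.
#' @param site_id the tree's site.
#' @return wood density in g cm^-3.
#' @export
assign_wood_density <- function(tree, table, site_id) {
  stopifnot(inherits(table, "wd_table"))
  sp <- as.character(tree$taxon_species)[1]
  if (!is.na(sp) && nzchar(sp) && sp %in% names(table$species))
    return(unname(table$species[sp]))
  gn <- as.character(tree$taxon_genus)[1]
  if (!is.na(gn) && nzchar(gn) && gn %in% names(table$genus))
    return(unname(table$genus[gn]))
  sid <- as.character(site_id)
  if (!sid %in% names(table$site))
    stop("no site-average wood density configured for site '", sid, "'")
  unname(table$site[sid])
}

# vectorised internal version used by plot_acs / the flux pipeline
assign_wood_density_all <- function(trees, table, site_id) {
  n <- nrow(trees)
  wd <- rep(NA_real_, n)
  sp <- as.character(trees$taxon_species)
  gn <- as.character(trees$taxon_genus)
  hit <- !is.na(sp) & sp %in% names(table$species)
  wd[hit] <- table$species[sp[hit]]
  hit <- is.na(wd) & !is.na(gn) & gn %in% names(table$genus)
  wd[hit] <- table$genus[gn[hit]]
  if (anyNA(wd)) {
    sid <- as.character(site_id)
    if (!sid %in% names(table$site))
      stop("no site-average wood density configured for site '", sid, "'")
    wd[is.na(wd)] <- table$site[sid]
  }
  wd
}

#' Plot-level aboveground carbon stock
#'
#' Sums [tree_acs()] over the live trees at or above the diameter threshold in
#' one census and scales by plot area to Mg C ha^-1.
#'
#' @param census inventory data.frame for one plot at one census date, with
#'   columns `dbh`, `status` (`"alive"`/`"dead"`), `taxon_species`,
#'   `taxon_genus`.
#' @param table a `wd_table` with the plot's site average present.
#' @param E climatic index of the site.
#' @param area plot area in ha (> 0).
#' @param site_id site identifier (for the wood-density fallback).
#' @param dbh_min diameter threshold in cm; trees with `dbh >= dbh_min` are
#'   counted. Default 20.
#' @param carbon_fraction fraction of biomass that is carbon.
#' @return plot ACS in Mg C ha^-1 (0, with a warning, for an empty census).
#' @export
plot_acs <- function(census, table, E, area, site_id,
                     dbh_min = 20, carbon_fraction = 0.5) {
  stopifnot(area > 0)
  keep <- census$status == "alive" & census$dbh >= dbh_min
  census <- census[keep, , drop = FALSE]
  if (nrow(census) == 0L) {
    warning("empty census: plot ACS set to 0")
    return(0)
  }
  wd <- assign_wood_density_all(census, table, site_id)
  sum(tree_acs(census$dbh, wd, E, carbon_fraction)) / area
}

#' Read a tree inventory from CSV
#'
#' Expected columns: `tree_id`, `plot_id`, `site_id`, `census_time` (decimal
#' years), `dbh` (cm), `taxon_species`, `taxon_genus` (empty when
#' unidentified), `status` (`alive`/`dead`). One row per tree per census.
#'
#' @param path path to a CSV file.
#' @return a data.frame with empty taxon strings converted to `NA`.
#' @export
read_inventory <- function(path) {
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "plot_id", "site_id", "census_time", "dbh", "status")
  miss <- setdiff(need, names(inv))
  if (length(miss))
    stop("inventory is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("taxon_species", "taxon_genus")) {
    if (!col %in% names(inv)) inv[[col]] <- NA_character_
    inv[[col]][!nzchar(trimws(as.character(inv[[col]])))] <- NA_character_
  }
  inv
}
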