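#' Load the packaged fixture tables
#'
#' Reads and checksum-verifies the packaged reference tables: the per-site
#' selectivity free-energy differences of the pump systems, the fitted
#' boosting-potential parameters per binding-site residue, and the inputs of
#' the pKa worked example.
#'
#' @param dir Directory holding the fixture files; defaults to the installed
#'   `extdata` directory.
#' @return List with data.frames `selectivity`, `boosting`, `pka_legs`.
#' @export
load_fixture_tables <- function(dir = NULL) {
  dir <- dir %||% system.file("extdata", package = "pumpsel")
  if (!nzchar(dir) || !dir.exists(dir))
    stop("fixture directory not found: ", dir)
  files <- c(selectivity = "site_selectivity_reference.tsv",
             boosting = "boosting_parameters_reference.tsv",
             pka_legs = "pka_cycle_inputs.tsv")
  paths <- file.path(dir, files)
  if (!all(file.exists(paths)))
    stop("missing fixture file(s): ",
         paste(files[!file.exists(paths)], collapse = ", "))
  manifest_path <- file.path(dir, "checksums.tsv")
  if (!file.exists(manifest_path)) stop("fixture checksum manifest missing")
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE,
                                colClasses = "character")
  for (i in seq_along(paths)) {
    h <- poly_hash(readLines(paths[i], warn = FALSE))
    want <- manifest$checksum[manifest$file == files[i]]
    if (!length(want) || h != want)
      stop("checksum mismatch for fixture ", files[i])
  }
  out <- lapply(paths, utils::read.delim, stringsAsFactors = FALSE)
  names(out) <- names(files)
  out
}

#' Boosting potential from a packaged table row
#'
#' Builds the [boosting_potential()] recorded for one binding-site residue
#' in the packaged boosting-parameter table.
#'
#' @param boosting The `boosting` data.frame from [load_fixture_tables()].
#' @param residue Residue label, e.g. `"D804"`.
#' @return A [boosting_potential()].
#' @export
boost_from_fixture <- function(boosting, residue) {
  row <- boosting[boosting$residue == residue, ]
  if (nrow(row) != 1) stop("no such residue in the boosting table: ", residue)
  N <- row$n_terms
  k <- as.numeric(row[paste0("k", seq_len(N))])
  chi0 <- as.numeric(row[paste0("chi0_", seq_len(N))])
  boosting_potential(k, chi0, residue = residue)
}

#' Selectivity report from a table of free-energy differences
#'
#' Applies the dissociation-constant mapping [kd_ratio()] to every entry of
#' a per-site selectivity table (such as the packaged reference table),
#' yielding the ln(K_D,K/K_D,Na) summary that the study plots per system and
#' site.
#'
#' @param tab data.frame with columns `system`, `site`, `ddg` and optionally
#'   `err` (kcal/mol); defaults to the packaged selectivity fixture.
#' @param temperature Kelvin.
#' @return A `selectivity_report`: the input table augmented with
#'   `ln_kd_ratio`, `kd_ratio` and `selective` columns.
#' @export
#' @examples
#' rep <- report_from_table()
#' subset(rep, system == "E1_S1")
report_from_table <- function(tab = NULL, temperature = .DEFAULT_T) {
  tab <- tab %||% load_fixture_tables()$selectivity
  stopifnot(all(c("system", "site", "ddg") %in% names(tab)))
  rt <- .KB * temperature
  tab$ln_kd_ratio <- tab$ddg / rt
  tab$kd_ratio <- exp(tab$ln_kd_ratio)
  tab$selective <- ifelse(tab$ddg < 0, "K", "Na")
  attr(tab, "temperature") <- temperature
  class(tab) <- c("selectivity_report", class(tab))
  tab
}

#' Run a full selectivity scenario
#'
#' End-to-end composition of the methodology for one scenario
#' configuration: build the reduced binding site and the bulk droplet,
#' estimate the site and bulk Na->K alchemical legs with the three-point
#' protocol, estimate the restraint-release legs for both species, and
#' assemble the standard-state selectivity `ddG(Na->K)` with its 10-block
#' error and the implied dissociation-constant ratio.  Fully reproducible
#' from `(config, seed)`.
#'
#' @param config Scenario configuration (list or JSON path), see
#'   [build_binding_site()].  `config$sampling$n_steps` controls the
#'   per-state sampling length.
#' @param seed Optional seed override (defaults to `config$seed`).
#' @param include_trans Run the restraint-release legs?  They cancel to
#'   within their error for a shared restraint and can be skipped for speed.
#' @return A list of class `scenario_result`: the assembled selectivity
#'   (see [assemble_binding_dg()]), the individual leg `fep_result`s, and a
#'   provenance record (config hash, seed, package version).
#' @export
run_scenario <- function(config, seed = NULL, include_trans = TRUE) {
  cfg <- normalize_scenario_config(config)
  seed <- as.integer(seed %||% cfg$seed)
  model <- build_binding_site(cfg)
  na <- default_ion_params("Na")
  k <- default_ion_params("K")
  ns <- cfg$sampling$n_steps
  thin <- cfg$sampling$thin
  site <- three_point_alchemy(model, na, k, n_steps = ns, thin = thin,
                              seed = seed)
  droplet <- bulk_droplet_model(n_solvent = cfg$droplet$n_solvent,
                                radius = cfg$droplet$radius,
                                temperature = cfg$temperature)
  bulk <- three_point_alchemy(droplet, na, k, n_steps = ns, thin = thin,
                              seed = seed + 100L)
  if (include_trans && !is.null(model$restraint)) {
    sched <- lambda_schedule("trans_decouple_Na", n = 6)
    tr_na <- decouple_restraint_leg(model, ion = na, lambdas = sched,
                                    n_steps = max(500L, ns %/% 2L),
                                    thin = thin, seed = seed + 200L)
    tr_k <- decouple_restraint_leg(model, ion = k, lambdas = sched,
                                   n_steps = max(500L, ns %/% 2L),
                                   thin = thin, seed = seed + 300L)
  } else tr_na <- tr_k <- list(dg = 0, err = 0)
  sel <- assemble_binding_dg(dg_site = site$dg, dg_bulk = bulk$dg,
                             g_trans_i = tr_na$dg, g_trans_j = tr_k$dg,
                             err_site = site$err, err_bulk = bulk$err,
                             err_trans_i = tr_na$err,
                             err_trans_j = tr_k$err,
                             temperature = cfg$temperature)
  structure(list(id = cfg$id, selectivity = sel, legs = list(
                   site = site, bulk = bulk, trans_na = tr_na,
                   trans_k = tr_k),
                 provenance = list(
                   config = cfg, seed = seed,
                   config_hash = poly_hash(as.character(jsonlite::toJSON(
                     cfg, auto_unbox = TRUE, digits = NA))),
                   package_version = as.character(utils::packageVersion("pumpsel")))),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$selectivity
  cat(sprintf("scenario '%s' (seed %d):\n", x$id, x$provenance$seed))
  cat(sprintf("  dG_site  (Na->K) = %8.3f +/- %.3f kcal/mol\n",
              s$dg_site, x$legs$site$err))
  cat(sprintf("  dG_bulk  (Na->K) = %8.3f +/- %.3f kcal/mol\n",
              s$dg_bulk, x$legs$bulk$err))
  cat(sprintf("  dG_trans (Na->K) = %8.3f kcal/mol\n", s$dg_trans))
  cat(sprintf("  ddG(Na->K) = %.3f +/- %.3f kcal/mol -> ln(KD,K/KD,Na) = %.2f (%s-selective)\n",
              s$ddg, s$err, s$ln_kd_ratio, s$selective))
  invisible(x)
}

#' Write a scenario result as deterministic report files
#'
#' Emits a TSV table with the assembled legs and selectivity plus a JSON
#' metadata file carrying the provenance record (config, seed, hash).
#'
#' @param result A [run_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- result$selectivity
  tab <- data.frame(scenario = result$id,
                    dg_site = s$dg_site, err_site = result$legs$site$err,
                    dg_bulk = s$dg_bulk, err_bulk = result$legs$bulk$err,
                    dg_trans = s$dg_trans, ddg = s$ddg, err = s$err,
                    ln_kd_ratio = s$ln_kd_ratio, kd_ratio = s$kd_ratio,
                    selective = s$selective)
  tsv <- file.path(dir, paste0(result$id, "_selectivity.tsv"))
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, paste0(result$id, "_metadata.json"))
  jsonlite::write_json(result$provenance, js, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(table = tsv, metadata = js))
}

#' Preset scenario configurations
#'
#' Convenience builders for the recurring scenario archetypes: a
#' "high-field" pocket with deprotonated acidic ligands (the arrangement
#' that favours Na+ binding) and a "low-field" pocket with the same ligands
#' protonated (which shifts preference towards K+).
#'
#' @param field `"high"` (two deprotonated acidic ligands) or `"low"` (both
#'   protonated).
#' @param n_ligands Ligand count (4--8).
#' @param seed Scenario seed.
#' @param ... Further config fields overriding the defaults.
#' @return A scenario config list for [run_scenario()] /
#'   [build_binding_site()].
#' @export
scenario_config <- function(field = c("high", "low"), n_ligands = 6,
                            seed = 1, ...) {
  field <- match.arg(field)
  charges <- rep(0, n_ligands)
  charges[c(1, 2)] <- -1
  cfg <- list(id = paste0(field, "_field"), seed = seed,
              n_ligands = n_ligands, ligand_charges = charges,
              protonated = rep(field == "low", n_ligands))
  utils::modifyList(cfg, list(...))
}
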