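#' Serialize EVB systems and fixtures to YAML
#'
#' Systems round-trip losslessly to at least 12 significant digits. Fixtures
#' additionally carry a `targets` block and, when present, a `calibration`
#' block with the solved parameters and solver metadata.
#'
#' @param system an [evb_system()].
#' @param path output file path.
#' @export
write_evb_yaml <- function(system, path) {
  obj <- list(
    states = lapply(system$states, function(s) {
      list(k_solute = s$k_solute, x0 = s$x0, alpha = s$alpha)
    }),
    h12 = system$h12, n_bath = system$n_bath,
    bath = list(k_ref = system$bath$k_ref,
                delta = as.list(system$bath$delta),
                center = as.list(system$bath$center),
                width = as.list(system$bath$width)),
    domain = as.list(system$domain), masses = as.list(system$masses))
  writeLines(yaml::as.yaml(obj, precision = 15), path)
  invisible(path)
}

#' @rdname write_evb_yaml
#' @export
read_evb_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  .system_from_list(obj)
}

.system_from_list <- function(obj) {
  num <- function(x) as.numeric(unlist(x))
  evb_system(
    state1 = diabatic_surface(obj$states[[1]]$k_solute, obj$states[[1]]$x0,
                              obj$states[[1]]$alpha),
    state2 = diabatic_surface(obj$states[[2]]$k_solute, obj$states[[2]]$x0,
                              obj$states[[2]]$alpha),
    h12 = obj$h12, n_bath = obj$n_bath,
    bath = list(k_ref = obj$bath$k_ref, delta = num(obj$bath$delta),
                center = num(obj$bath$center), width = num(obj$bath$width)),
    domain = num(obj$domain), masses = num(obj$masses))
}

#' @param fixture a `"surrogate_fixture"` from [build_fixture()].
#' @rdname write_evb_yaml
#' @export
write_fixture_yaml <- function(fixture, path) {
  t <- fixture$targets
  obj <- list(
    name = fixture$name, seed = fixture$seed,
    system = yaml::read_yaml(text = {
      tmp <- tempfile(fileext = ".yml"); on.exit(unlink(tmp))
      write_evb_yaml(fixture$system, tmp)
      paste(readLines(tmp), collapse = "\n")
    }),
    targets = list(dG_act = t$dG_act, TdS_act = t$TdS_act,
                   dG_rxn = t$dG_rxn, TdS_rxn = t$TdS_rxn,
                   T_ref = t$T_ref, standard_state = t$standard_state))
  if (!is.null(fixture$calibration)) {
    cal <- fixture$calibration
    obj$calibration <- list(alpha = cal$alpha, h12 = cal$h12,
                            achieved_dG_act = cal$achieved_dG_act,
                            achieved_dG_rxn = cal$achieved_dG_rxn,
                            n_iterations = cal$n_iterations)
  }
  writeLines(yaml::as.yaml(obj, precision = 15), path)
  invisible(path)
}

#' @rdname write_evb_yaml
#' @export
read_fixture_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  t <- obj$targets
  has_rxn <- !is.null(t$dG_rxn) && is.finite(t$dG_rxn)
  targets <- fixture_targets(
    dG_act = t$dG_act, TdS_act = t$TdS_act,
    dG_rxn = if (has_rxn) t$dG_rxn else NULL,
    TdS_rxn = if (has_rxn) t$TdS_rxn else 0,
    T_ref = t$T_ref, standard_state = t$standard_state)
  cal <- if (!is.null(obj$calibration)) {
    structure(c(obj$calibration,
                list(target_dG_act = t$dG_act,
                     target_dG_rxn = if (has_rxn) t$dG_rxn else NA_real_,
                     T_ref = t$T_ref)),
              class = "calibration_result")
  }
  structure(list(system = .system_from_list(obj$system), targets = targets,
                 name = obj$name, calibration = cal,
                 seed = as.integer(obj$seed)),
            class = "surrogate_fixture")
}

#' Write a fixture manifest
#'
#' Writes every fixture to `<dir>/<name>.yml` plus a JSON manifest mapping
#' name to file and targets.
#'
#' @param fixtures named list of `"surrogate_fixture"` objects.
#' @param dir output directory (created if needed).
#' @return path of the manifest JSON, invisibly.
#' @export
write_fixture_manifest <- function(fixtures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- lapply(fixtures, function(fx) {
    file <- paste0(fx$name, ".yml")
    write_fixture_yaml(fx, file.path(dir, file))
    t <- fx$targets
    list(file = file,
         targets = list(dG_act = t$dG_act, TdS_act = t$TdS_act,
                        dG_rxn = t$dG_rxn, TdS_rxn = t$TdS_rxn,
                        T_ref = t$T_ref, standard_state = t$standard_state))
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
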