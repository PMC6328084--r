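manifest_roles <- c("tumour", "pdx", "pdo")

#' Read a sample manifest
#'
#' The manifest is a YAML file grouping samples into patients. Each patient
#' entry carries `patient_id`, a `cohort` label ("primary" or "metastasis"),
#' a `samples` map from role (tumour, pdx, pdo) to sample id, and a `files`
#' map from role to per-datatype paths (`ssm` VCF, `sv` BEDPE, `cn` segment
#' file). Relative paths are resolved against the manifest's directory.
#'
#' Every patient must have a tumour plus at least one model role; a trio has
#' all three roles.
#'
#' @param path Path to the manifest YAML.
#' @return A list of patient entries (class `concord_manifest`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort("manifest not found: %s", path)
  doc <- yaml::read_yaml(path)
  patients <- doc$patients %||% doc
  base_dir <- dirname(normalizePath(path))
  entries <- lapply(patients, function(p) {
    roles <- intersect(manifest_roles, names(p$samples %||% list()))
    if (!"tumour" %in% roles || length(roles) < 2)
      abort("patient '%s': manifest needs a tumour plus at least one model role",
            p$patient_id %||% "?")
    files <- p$files %||% list()
    files <- lapply(files, function(role_files) {
      lapply(role_files, function(f) {
        if (is.null(f)) return(NULL)
        if (file.exists(f)) f else file.path(base_dir, f)
      })
    })
    structure(
      list(patient_id = p$patient_id, cohort = p$cohort %||% "primary",
           samples = p$samples[roles], files = files[roles]),
      class = "manifest_entry"
    )
  })
  structure(entries, class = "concord_manifest")
}

#' Write a sample manifest
#'
#' @param entries A list of manifest entries (as built by [simulate_trio()]
#'   or [read_manifest()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  base_dir <- normalizePath(dirname(path), mustWork = FALSE)
  relativize <- function(f) {
    fn <- normalizePath(f, mustWork = FALSE)
    if (identical(dirname(fn), base_dir)) basename(fn) else f
  }
  plain <- lapply(entries, function(e) {
    files <- lapply(e$files, function(role_files)
      lapply(role_files, relativize))
    list(patient_id = e$patient_id, cohort = e$cohort,
         samples = e$samples, files = files)
  })
  yaml::write_yaml(list(patients = plain), path)
  invisible(path)
}
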