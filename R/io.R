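#' Read an XYZ geometry file
#'
#' Standard XYZ: first line the atom count, second line a comment, then one
#' `element x y z` record per atom (coordinates in angstrom). Order is
#' preserved; trailing blank lines are ignored.
#'
#' @param path Path to the file.
#' @return Data frame with columns `element`, `x`, `y`, `z` (angstrom).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 2) stop("XYZ parse error: file too short (", path, ")")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ parse error at line 1: atom count expected, got '",
                     lines[1], "'")
  if (length(lines) - 2 != n) {
    stop("XYZ parse error: header declares ", n, " atoms but ",
         length(lines) - 2, " records found")
  }
  rec <- lapply(seq_len(n), function(i) {
    ln <- i + 2
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(parts) < 4) {
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    }
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz))) {
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    }
    data.frame(element = parts[1], x = xyz[1], y = xyz[2], z = xyz[3])
  })
  do.call(rbind, rec)
}

#' Write an XYZ geometry file
#' @param df Data frame with `element`, `x`, `y`, `z` columns (angstrom).
#' @param path Output path.
#' @param comment Comment line.
#' @export
write_xyz <- function(df, path, comment = "") {
  lines <- c(nrow(df), comment,
             sprintf("%-4s %18.12f %18.12f %18.12f",
                     df$element, df$x, df$y, df$z))
  writeLines(lines, path)
}

# "400 MHz" / "28.2 T" style field specifications -> tesla
parse_field <- function(x) {
  if (is.numeric(x)) {
    stop("untagged numeric field value '", x,
         "'; write e.g. '400 MHz' or '9.4 T' to avoid tesla/MHz confusion")
  }
  m <- regmatches(x, regexec(
    "^\\s*([0-9.eE+-]+)\\s*(T|tesla|MHz|GHz)\\s*$", as.character(x)))[[1]]
  if (length(m) != 3) {
    stop("cannot parse field specification '", x,
         "'; expected '<number> T', '<number> MHz' or '<number> GHz'")
  }
  val <- as.numeric(m[2])
  if (is.na(val) || val < 0) stop("invalid field value in '", x, "'")
  switch(m[3],
         T = , tesla = val,
         MHz = larmor_to_field(val),
         GHz = larmor_to_field(1000 * val))
}

#' Parse field specifications to tesla
#'
#' Accepts strings with an explicit unit tag: `"400 MHz"`, `"1.2 GHz"`
#' (proton Larmor frequencies) or `"28.2 T"`. Untagged numbers are an
#' error by design.
#'
#' @param fields Character vector of field specifications.
#' @return Numeric vector, tesla.
#' @export
parse_fields <- function(fields) {
  vapply(fields, parse_field, numeric(1), USE.NAMES = FALSE)
}

#' Read a run configuration from YAML
#'
#' Expected blocks: `spin` (S, g, and either D matrix in cm^-1 or
#' D/E + optional Euler angles in degrees), `nuclei` (list with label,
#' position or an `xyz` file reference, A_iso_MHz, isotope/gamma),
#' `center` (angstrom), `temperature` (K), `fields` (unit-tagged strings),
#' `method` ("finite-field", "second-order" or "both"), `grid` (point
#' count), `contributions` ("FC", "PC" or "both").
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list (see [run_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$nuclei$xyz)) {
    geom <- read_xyz(file.path(dirname(path), cfg$nuclei$xyz))
    A <- cfg$nuclei$A_iso_MHz %||% rep(0, nrow(geom))
    cfg$nuclei <- lapply(seq_len(nrow(geom)), function(i) {
      list(label = paste0(geom$element[i], i),
           position_A = as.numeric(geom[i, c("x", "y", "z")]),
           A_iso_MHz = A[[min(i, length(A))]],
           isotope = if (geom$element[i] == "H") "1H" else geom$element[i])
    })
  }
  do.call(run_config, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build and validate a run configuration
#'
#' @param spin List with `S`, `g` (scalar, 3-vector of principal values or
#'   3x3 matrix), and either `D_cm1` (3x3) or `D_axial_cm1` /
#'   `E_rhombic_cm1` plus optional `euler_deg` (chi, theta, phi) rotating
#'   the D and g principal axes.
#' @param nuclei List of lists with `label`, `position_A`, `A_iso_MHz`,
#'   and `isotope` or `gamma_si`.
#' @param fields Character vector of unit-tagged field strengths.
#' @param temperature Kelvin (default 298).
#' @param method `"finite-field"`, `"second-order"` or `"both"`.
#' @param grid Orientation-grid point count (default 26).
#' @param contributions `"FC"`, `"PC"` or `"both"`.
#' @param center Paramagnetic center, angstrom (default origin).
#' @param seed Optional integer recorded in output metadata.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spin, nuclei, fields, temperature = 298,
                       method = c("both", "finite-field", "second-order"),
                       grid = 26, contributions = c("both", "FC", "PC"),
                       center = c(0, 0, 0), seed = NULL) {
  method <- match.arg(method)
  contributions <- match.arg(contributions)
  problems <- character(0)
  if (missing(spin) || is.null(spin$S)) problems <- c(problems, "spin block with S is required")
  if (missing(nuclei) || length(nuclei) == 0) problems <- c(problems, "at least one nucleus is required")
  if (missing(fields) || length(fields) == 0) problems <- c(problems, "a non-empty fields list is required")
  if (temperature <= 0) problems <- c(problems, "temperature must be > 0")
  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  g <- spin$g %||% 2.0
  if (is.list(g)) g <- do.call(rbind, g)
  if (!is.matrix(g) && length(g) == 3) g <- diag(as.numeric(g))
  D_cm1 <- spin$D_cm1
  if (!is.null(D_cm1) && is.list(D_cm1)) D_cm1 <- do.call(rbind, D_cm1)
  if (is.null(D_cm1)) {
    Dax <- spin$D_axial_cm1 %||% 0
    Erh <- spin$E_rhombic_cm1 %||% 0
    D_cm1 <- diag(c(-Dax / 3 + Erh, -Dax / 3 - Erh, 2 * Dax / 3))
  }
  if (!is.null(spin$euler_deg)) {
    R <- do.call(euler_to_rotation, as.list(as.numeric(spin$euler_deg) * pi / 180))
    D_cm1 <- R %*% D_cm1 %*% t(R)
    g <- R %*% g %*% t(R)
  }
  system <- spin_system(spin$S, g = g, D_cm1 = D_cm1)
  nucs <- lapply(nuclei, function(nu) {
    nucleus(label = nu$label %||% "X",
            position_A = as.numeric(nu$position_A),
            A_iso_MHz = nu$A_iso_MHz %||% 0,
            isotope = nu$isotope %||% "1H",
            gamma_si = nu$gamma_si)
  })
  fields <- vapply(fields, as.character, character(1))
  structure(list(system = system, nuclei = nucs,
                 fields_T = parse_fields(fields), fields_label = fields,
                 temperature = temperature, method = method, grid = grid,
                 contributions = contributions,
                 center_A = as.numeric(center), seed = seed),
            class = "run_config")
}

#' Write a run configuration to a YAML file
#'
#' Numbers are written with 17 significant digits so that
#' `read_config(write_config(cfg, path))` reproduces the configuration to
#' full double precision.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(serialize_config(cfg), precision = 17), path)
  invisible(path)
}

#' Serialize a run configuration back to a YAML-ready list
#'
#' `run_config(serialize_config(cfg)...)` reproduces the configuration;
#' used for the config round-trip guarantee and to store metadata.
#'
#' @param cfg A `run_config`.
#' @return Plain list mirroring the YAML schema.
#' @export
serialize_config <- function(cfg) {
  list(
    spin = list(S = cfg$system$S,
                g = lapply(seq_len(3), function(i) as.numeric(cfg$system$g[i, ])),
                D_cm1 = lapply(seq_len(3), function(i)
                  as.numeric(cm1_from_au(cfg$system$D_au)[i, ]))),
    nuclei = lapply(cfg$nuclei, function(nu)
      list(label = nu$label, position_A = nu$position_A,
           A_iso_MHz = nu$A_iso_MHz, gamma_si = nu$gamma_si)),
    fields = as.list(cfg$fields_label),
    temperature = cfg$temperature, method = cfg$method, grid = cfg$grid,
    contributions = cfg$contributions, center = cfg$center_A,
    seed = cfg$seed)
}
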