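#' Run a shift calculation from a configuration
#'
#' Dispatches to the finite-field and/or second-order routes for every
#' nucleus and field in the configuration and assembles a shift table with
#' the Fermi-contact/pseudocontact decomposition. Optionally writes the
#' table as CSV with a JSON metadata sidecar.
#'
#' @param cfg A [run_config()] (or path to a YAML file, which is read with
#'   [read_config()]).
#' @param out Optional CSV output path; a `<out>.meta.json` sidecar with
#'   method, grid, temperature, package version and seed is written next
#'   to it.
#' @param verbose If `TRUE`, prints per-step progress messages.
#' @return Data frame of class `shift_table`: one row per (nucleus,
#'   field) with columns `label`, `field`, `B0_T`, `delta_FC_ppm`,
#'   `delta_PC_ppm`, `delta_ppm` (per requested method, suffixed `_ff` /
#'   `_so` when both run), and for the second-order route `delta0_ppm`,
#'   `c_indirect_ppm_T2`, `c_direct_ppm_T2`.
#' @export
run_shifts <- function(cfg, out = NULL, verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(...)
  do_ff <- cfg$method %in% c("finite-field", "both")
  do_so <- cfg$method %in% c("second-order", "both")
  want_fc <- cfg$contributions %in% c("FC", "both")
  want_pc <- cfg$contributions %in% c("PC", "both")
  if (want_fc && all(vapply(cfg$nuclei, function(nu) nu$A_iso_MHz == 0,
                            logical(1)))) {
    warning("FC contribution requested but all nuclei have A_iso = 0; ",
            "FC shifts will be zero")
  }
  nn <- length(cfg$nuclei)
  labels <- vapply(cfg$nuclei, function(nu) nu$label, character(1))

  rows <- expand.grid(label = labels, field = cfg$fields_label,
                      stringsAsFactors = FALSE)
  rows$B0_T <- cfg$fields_T[match(rows$field, cfg$fields_label)]

  if (do_ff) {
    say("finite-field route on a ", cfg$grid, "-point grid")
    grid <- lebedev_grid(cfg$grid)
    ff <- do.call(rbind, lapply(cfg$fields_T, function(B0) {
      finite_field_shift(cfg$system, cfg$nuclei, B0, cfg$temperature,
                         grid = grid, contributions = cfg$contributions,
                         center_A = cfg$center_A)
    }))
    key <- paste(rows$label, rows$B0_T)
    m <- match(key, paste(ff$label, ff$B0_T))
    sfx <- if (do_so) "_ff" else ""
    rows[[paste0("delta_FC_ppm", sfx)]] <- ff$delta_FC_ppm[m]
    rows[[paste0("delta_PC_ppm", sfx)]] <- ff$delta_PC_ppm[m]
    rows[[paste0("delta_ppm", sfx)]] <- ff$delta_ppm[m]
  }
  if (do_so) {
    say("second-order route (analytic free-energy derivatives)")
    so_rows <- lapply(seq_len(nn), function(a) {
      nu <- cfg$nuclei[[a]]
      parts <- list()
      if (want_fc) parts$FC <- second_order_shift(
        assemble_response(cfg$system, nu, cfg$temperature, "FC"))
      if (want_pc) parts$PC <- second_order_shift(
        assemble_response(cfg$system, nu, cfg$temperature, "PC",
                          center_A = cfg$center_A))
      parts
    })
    sfx <- if (do_ff) "_so" else ""
    for (col in c("delta_FC_ppm", "delta_PC_ppm", "delta_ppm")) {
      rows[[paste0(col, sfx)]] <- NA_real_
    }
    rows$delta0_ppm <- NA_real_
    rows$c_indirect_ppm_T2 <- NA_real_
    rows$c_direct_ppm_T2 <- NA_real_
    for (r in seq_len(nrow(rows))) {
      a <- match(rows$label[r], labels)
      parts <- so_rows[[a]]
      dFC <- if (want_fc) shift_at_fields(parts$FC, rows$B0_T[r]) else 0
      dPC <- if (want_pc) shift_at_fields(parts$PC, rows$B0_T[r]) else 0
      rows[[paste0("delta_FC_ppm", sfx)]][r] <- dFC
      rows[[paste0("delta_PC_ppm", sfx)]][r] <- dPC
      rows[[paste0("delta_ppm", sfx)]][r] <- dFC + dPC
      rows$delta0_ppm[r] <- sum(vapply(parts, function(p) p$delta0_ppm,
                                       numeric(1)))
      rows$c_indirect_ppm_T2[r] <-
        sum(vapply(parts, function(p) p$c_indirect_ppm_T2, numeric(1)))
      rows$c_direct_ppm_T2[r] <-
        sum(vapply(parts, function(p) p$c_direct_ppm_T2, numeric(1)))
    }
  }
  if (do_ff && do_so) {
    rows$ff_so_diff_ppm <- rows$delta_ppm_ff - rows$delta_ppm_so
  }
  class(rows) <- c("shift_table", class(rows))
  attr(rows, "metadata") <- list(
    method = cfg$method, grid = cfg$grid, temperature = cfg$temperature,
    contributions = cfg$contributions,
    package_version = as.character(utils::packageVersion("paranmr")),
    seed = cfg$seed)
  if (!is.null(out)) write_shift_table(rows, out)
  rows
}

#' Write a shift table as CSV plus a JSON metadata sidecar
#'
#' Values are printed with 12 significant digits so that reading the CSV
#' back reproduces them to full printed precision.
#'
#' @param tab A `shift_table` from [run_shifts()].
#' @param path CSV output path.
#' @export
write_shift_table <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  for (j in which(num)) out[[j]] <- signif(tab[[j]], 12)
  utils::write.csv(out, path, row.names = FALSE)
  meta <- attr(tab, "metadata")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}
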