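# Persistence of analysis products: master residue table, B-factor-annotated
# coordinates, molecular-viewer script, per-site summaries and plot sidecars.
# Every figure has a numeric CSV sidecar; tests assert on the sidecars.

#' Write the master interaction table
#'
#' One row per selected residue with per-residue metrics and the site-level
#' copies for residues belonging to a binding site (empty otherwise).
#' Numeric columns round-trip losslessly through [readr::read_csv()].
#'
#' @param table Tibble (see [run_pipeline()] for the canonical columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (nrow(table) == 0L) warn("writing a header-only interaction table")
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' Write coordinates with a metric in the B-factor column
#'
#' Every atom of a residue carries that residue's metric value in the PDB
#' B-factor field, so viewers can colour the structure by it. The
#' fixed-width field limits values to `[0, 999.99]`; out-of-range values are
#' clamped and `NA`/`NaN` written as 0 with a warning.
#'
#' @param model A `system_model` (frame 1 coordinates are written).
#' @param metric Named numeric: one value per residue serial
#'   (`model$residues$index`).
#' @param path Output `.pdb` path.
#' @return `path`, invisibly.
#' @export
write_bfactor_coordinates <- function(model, metric, path) {
  res <- model$residues
  vals <- metric[as.character(res$index)]
  if (anyNA(vals)) {
    warn("NA metric values written as B-factor 0")
    vals[is.na(vals)] <- 0
  }
  vals <- pmin(pmax(vals, 0), 999.99)
  atoms_ix <- unlist(res$atom_indices)
  b <- rep(vals, times = vapply(res$atom_indices, length, integer(1)))
  at <- model$atoms[atoms_ix, ]
  xyz <- model$coords[atoms_ix, , 1]
  bio3d::write.pdb(
    file = path, xyz = as.numeric(t(xyz)) * 10,
    resno = at$resid, resid = at$resname, elety = at$atom_name,
    b = round(b, 2)
  )
  invisible(path)
}

# Read back per-residue B-factors from a PDB written above (round-trip aid).
read_bfactor_coordinates <- function(path) {
  p <- bio3d::read.pdb(path)
  tapply(p$atom$b, p$atom$resno, function(v) v[1])
}

site_palette <- c(
  "0x1f77b4", "0xff7f0e", "0x2ca02c", "0xd62728", "0x9467bd",
  "0x8c564b", "0xe377c2", "0x7f7f7f", "0xbcbd22", "0x17becf",
  "0x393b79", "0x637939", "0x8c6d31", "0x843c39", "0x7b4173",
  "0x3182bd", "0xe6550d", "0x31a354", "0x756bb1", "0x636363"
)

#' Write a molecular-viewer script for the binding sites
#'
#' Emits a PyMOL-dialect script that loads the B-factor coordinate file,
#' shows each binding site's residues as same-coloured spheres and scales
#' each sphere by the residue's metric (with a small visibility floor so a
#' zero metric still renders).
#'
#' @param sites Site tibble (`site_id`, `residues` list-column).
#' @param table Master residue table (`residue`, `resid`, metric column).
#' @param pdb_path Path to the coordinate file, referenced relatively.
#' @param path Output script path.
#' @param metric Column of `table` driving the sphere scale.
#' @return `path`, invisibly.
#' @export
write_visualization_script <- function(sites, table, pdb_path, path,
                                       metric = "residence_time") {
  lines <- c(
    "from pymol import cmd",
    sprintf('cmd.load("%s", "complex")', basename(pdb_path)),
    'cmd.hide("everything")',
    'cmd.show("cartoon", "complex")',
    'cmd.color("grey80", "complex")'
  )
  if (nrow(sites) == 0L) {
    warn("no binding sites; visualization script shows the cartoon only")
  } else {
    vals <- table[[metric]]
    vmax <- max(c(vals, 0), na.rm = TRUE)
    for (s in seq_len(nrow(sites))) {
      col <- site_palette[(sites$site_id[s] - 1L) %% length(site_palette) + 1L]
      lines <- c(lines, sprintf(
        'cmd.set_color("site%d_color", "%s")', sites$site_id[s], col
      ))
      for (r in sites$residues[[s]]) {
        row <- table[table$residue == r, ]
        v <- row[[metric]][1]
        scale <- if (!is.finite(v) || vmax <= 0) 0.3 else max(0.3, 1.0 * v / vmax)
        sel <- sprintf("(complex and resi %d)", row$resid[1])
        lines <- c(
          lines,
          sprintf('cmd.show("spheres", "%s")', sel),
          sprintf('cmd.set("sphere_scale", %.3f, "%s")', scale, sel),
          sprintf('cmd.color("site%d_color", "%s")', sites$site_id[s], sel)
        )
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Plot a residue metric along the sequence
#'
#' Draws `metric` against residue index and always writes the plotted
#' numbers next to the figure as a CSV sidecar, so downstream checks assert
#' on numbers rather than pixels. Chain breaks (gaps in `resid`) are kept as
#' gaps on the x axis.
#'
#' @param table Master residue table.
#' @param metric Column to plot.
#' @param path Optional figure path (`.png`/`.pdf`); the sidecar gets the
#'   same path with extension `.csv`. `NULL` returns the plot only.
#' @return A ggplot object, invisibly when `path` is given.
#' @export
plot_interactions <- function(table, metric, path = NULL) {
  if (!metric %in% names(table) || all(!is.finite(table[[metric]]))) {
    stop_ls("metric '%s' is empty", metric)
  }
  df <- tibble::tibble(
    resid = table$resid, value = table[[metric]]
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$resid, .data$value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue", y = metric) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    readr::write_csv(df, sub("\\.[A-Za-z]+$", ".csv", path))
    ggplot2::ggsave(path, gg, width = 7, height = 3, dpi = 150)
    return(invisible(gg))
  }
  gg
}

#' Write a plain-text per-site summary
#'
#' @param site One row of the site tibble (with metrics attached).
#' @param fit The site `koff_fit`.
#' @param area_summary Named list/vector with `mean` and `sd` surface area.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_info <- function(site, fit, area_summary, path) {
  g <- glance(fit)
  lines <- c(
    sprintf("binding site %d", site$site_id),
    sprintf("residues (%d): %s", length(site$residues[[1]]),
      paste(site$residues[[1]], collapse = " ")),
    sprintf("residence time: %.4g ns", g$residence_time),
    sprintf("koff: %.4g ns^-1", g$koff),
    sprintf("r_squared: %.4f", g$r_squared),
    sprintf("n_events: %d", g$n_events),
    sprintf("bootstrap koff: %.4g +/- %.4g ns^-1", g$boot_koff_mean, g$boot_koff_sd),
    sprintf("mean duration: %.4g ns", site$mean_duration),
    sprintf("occupancy: %.2f %%", site$occupancy),
    sprintf("lipid count: %.3f", site$lipid_count),
    sprintf(
      "surface area: %.4g +/- %.4g nm^2",
      area_summary[["mean"]], area_summary[["sd"]]
    )
  )
  writeLines(lines, path)
  invisible(path)
}
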