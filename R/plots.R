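# Simple diagnostic plots (base graphics). Plots are conveniences; every
# quantity shown is available in the machine-readable tables.

#' Plot GC-corrected telomere content of a pair
#'
#' Stacked bars of tumor and control TRPM, partitioned by the hexamer
#' composition of the intratelomeric fraction.
#'
#' @param res A `pair_result`.
#' @export
plot_content_bars <- function(res) {
  stopifnot(inherits(res, "pair_result"))
  comp <- function(s) {
    h <- s$tvr$hexamers
    if (length(h) == 0 || s$content$undefined || sum(h) == 0) {
      return(setNames(s$content$trpm, "TTAGGG"))
    }
    s$content$trpm * h / sum(h)
  }
  ct <- comp(res$tumor); cc <- comp(res$control)
  hex <- union(names(ct), names(cc))
  m <- matrix(0, nrow = length(hex), ncol = 2,
              dimnames = list(hex, c("tumor", "control")))
  m[names(ct), 1] <- ct; m[names(cc), 2] <- cc
  graphics::barplot(m, col = grDevices::hcl.colors(length(hex), "Spectral"),
                    legend.text = hex, ylab = "TRPM",
                    main = "GC-corrected telomere content")
}

#' Plot the repeats-per-read histogram
#'
#' @param res A `sample_result`.
#' @export
plot_repeat_histogram <- function(res) {
  stopifnot(inherits(res, "sample_result"))
  h <- res$repeat_histogram
  graphics::barplot(h, names.arg = names(h),
                    xlab = "telomere repeats per read", ylab = "reads",
                    main = paste("Intratelomeric repeat counts:", res$sample))
}

#' Plot per-hexamer log2 tumor/control ratios
#'
#' @param res A `pair_result`.
#' @param what `"tvr"` (arbitrary context) or `"singleton"`.
#' @export
plot_log2_ratios <- function(res, what = c("tvr", "singleton")) {
  stopifnot(inherits(res, "pair_result"))
  what <- match.arg(what)
  tab <- if (what == "tvr") res$tvr_table else res$singleton_table
  tab <- tab[!is.na(tab$log2_tc) & tab$hexamer != "TTAGGG", , drop = FALSE]
  if (nrow(tab) == 0) {
    graphics::plot.new()
    graphics::title(main = "no defined log2 ratios")
    return(invisible(NULL))
  }
  graphics::barplot(setNames(tab$log2_tc, tab$hexamer), las = 2,
                    ylab = "log2 T/C",
                    main = if (what == "tvr") "TVRs (arbitrary context)"
                           else "Singleton TVRs")
  graphics::abline(h = 0)
}

#' Plot the per-chromosome spectrum of placeable telomeric reads
#'
#' @param res A `sample_result`.
#' @export
plot_spectrum <- function(res) {
  stopifnot(inherits(res, "sample_result"))
  sp <- res$spectrum
  m <- t(as.matrix(sp[, c("subtelomeric", "junction_spanning",
                          "intrachromosomal")]))
  colnames(m) <- sp$chrom
  graphics::barplot(m, beside = TRUE, las = 2,
                    col = c("steelblue", "orange", "grey50"),
                    legend.text = rownames(m), ylab = "reads",
                    main = paste("Telomeric read spectrum:", res$sample))
}

#' Write the standard plot set of a paired run as PNG files
#'
#' @param res A `pair_result`.
#' @param out_dir Output directory.
#' @return Paths of written files, invisibly.
#' @export
plot_pair_result <- function(res, out_dir) {
  draw <- function(name, fun) {
    p <- file.path(out_dir, paste0(name, ".png"))
    grDevices::png(p, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    fun()
    p
  }
  paths <- c(
    draw("content", function() plot_content_bars(res)),
    draw("repeat_histogram", function() plot_repeat_histogram(res$tumor)),
    draw("tvr_log2", function() plot_log2_ratios(res, "tvr")),
    draw("singleton_log2", function() plot_log2_ratios(res, "singleton")),
    draw("spectrum", function() plot_spectrum(res$tumor))
  )
  invisible(paths)
}
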