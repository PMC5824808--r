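#' PCA colours for clonal maps
#'
#' Column-centred principal component analysis of the 0/1 character matrix
#' (`NA` treated as absence), with the first three components min-max scaled
#' to `[0, 1]` and assigned to red, green and blue. Sign convention: within
#' each component the element with the largest absolute loading is made
#' positive, so colours are deterministic and invariant to sample order.
#' Missing components of a low-rank matrix are padded with 0.5 (grey).
#'
#' @param matrix Samples x markers 0/1/NA matrix (>= 3 samples).
#' @return Samples x 3 matrix of RGB values in `[0, 1]`.
#' @export
pca_colors <- function(matrix) {
  if (nrow(matrix) < 3) stop("need >= 3 samples")
  m <- matrix
  m[is.na(m)] <- 0
  m <- scale(m, center = TRUE, scale = FALSE)
  rgb <- matrix(0.5, nrow(m), 3,
                dimnames = list(rownames(matrix), c("r", "g", "b")))
  if (ncol(m) == 0 || all(m == 0)) return(rgb)
  sv <- svd(m)
  keep <- sv$d > max(sv$d) * 1e-8
  n_comp <- min(3, sum(keep))
  for (k in seq_len(n_comp)) {
    load <- sv$v[, k]
    flip <- sign(load[which.max(abs(load))])
    comp <- sv$u[, k] * sv$d[k] * flip
    rng <- range(comp)
    if (diff(rng) > 0) rgb[, k] <- (comp - rng[1]) / diff(rng)
  }
  rgb
}

#' Geometric layout of a patient's clonal map
#'
#' Places each biopsy as an oval at its axial position (cm from the GEJ)
#' split into four baguette sections, and each crypt as a square inside its
#' section; every sample carries its PCA colour. Biopsies without a recorded
#' position are placed on a separate "unlocalised" rail with a warning. The
#' JSON export is lossless and is the machine-readable surface; the SVG is
#' for human inspection.
#'
#' @param samples Sample metadata data.frame (one patient).
#' @param colors Samples x 3 RGB matrix from [pca_colors()].
#' @return A `map_layout` list: `biopsies` (position, oval geometry),
#'   `crypts` (square per crypt) and `samples` (sample id -> colour).
#' @export
layout_map <- function(samples, colors) {
  bios <- unique(samples[samples$role == "biopsy_epithelium",
                         c("biopsy_id", "gej_distance_cm", "time_point",
                           "sample_id")])
  unloc <- is.na(bios$gej_distance_cm)
  if (any(unloc))
    warning("biopsies without position placed on unlocalised rail: ",
            paste(bios$biopsy_id[unloc], collapse = ","))
  ord <- order(unloc, bios$gej_distance_cm, bios$biopsy_id)
  bios <- bios[ord, ]
  biopsy_rows <- lapply(seq_len(nrow(bios)), function(i) {
    col <- colors[bios$sample_id[i], ]
    list(biopsy_id = bios$biopsy_id[i],
         axial_cm = if (is.na(bios$gej_distance_cm[i])) NULL
                    else bios$gej_distance_cm[i],
         unlocalised = unname(is.na(bios$gej_distance_cm[i])),
         slot = i, n_sections = 4L,
         epithelium_sample = bios$sample_id[i],
         rgb = as.numeric(col))
  })
  crypts <- samples[samples$role == "crypt", ]
  crypt_rows <- lapply(seq_len(nrow(crypts)), function(i) {
    col <- colors[crypts$sample_id[i], ]
    list(sample_id = crypts$sample_id[i],
         biopsy_id = crypts$biopsy_id[i],
         section = as.integer(crypts$baguette_section[i]),
         slot = crypts$crypt_slot[i],
         rgb = as.numeric(col))
  })
  structure(list(biopsies = biopsy_rows, crypts = crypt_rows),
            class = "map_layout")
}

#' Export a clonal-map layout
#'
#' @param layout A `map_layout`.
#' @param path Output path; `.json` or `.svg` chosen by `format`.
#' @param format `"json"` (lossless) or `"svg"` (rendering).
#' @return Invisibly `path`.
#' @export
write_map <- function(layout, path, format = c("json", "svg")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  w <- 120; h0 <- 60
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    w * 2, h0 * (length(layout$biopsies) + 1)))
  for (b in layout$biopsies) {
    y <- h0 * b$slot
    col <- grDevices::rgb(b$rgb[1], b$rgb[2], b$rgb[3])
    lines <- c(lines, sprintf(
      '<ellipse cx="%d" cy="%d" rx="%d" ry="%d" fill="%s" stroke="black"/>',
      w, y, 50, 18, col),
      sprintf('<text x="%d" y="%d" font-size="10">%s (%s cm)</text>',
              w - 55, y - 22, b$biopsy_id,
              if (isTRUE(b$unlocalised)) "?" else format(b$axial_cm)))
    for (cr in layout$crypts) {
      if (cr$biopsy_id != b$biopsy_id) next
      cx <- w - 50 + (cr$section - 1) * 25 + (cr$slot == "b") * 11
      ccol <- grDevices::rgb(cr$rgb[1], cr$rgb[2], cr$rgb[3])
      lines <- c(lines, sprintf(
        '<rect x="%d" y="%d" width="9" height="9" fill="%s" stroke="black"/>',
        as.integer(cx), as.integer(y - 5), ccol))
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

#' Read back a JSON clonal-map layout
#'
#' @param path JSON path written by [write_map()].
#' @return A `map_layout`.
#' @export
read_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$biopsies <- lapply(x$biopsies, function(b) {
    b$rgb <- as.numeric(unlist(b$rgb)); b
  })
  x$crypts <- lapply(x$crypts, function(b) {
    b$rgb <- as.numeric(unlist(b$rgb)); b
  })
  structure(x, class = "map_layout")
}
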