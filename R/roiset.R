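#' Define a set of regions of interest
#'
#' An ROI set names the nodes of the connectome and assigns each one to a
#' lobe (`"parietal"` or `"premotor"`), a free-text subdomain, and a
#' hemisphere. Every connectivity matrix handled by the package is aligned
#' to the row order of its ROI set.
#'
#' @param name Character vector of unique ROI labels.
#' @param lobe Character vector, one of `"parietal"` or `"premotor"` per ROI.
#' @param subdomain Optional character vector of anatomical subdomains.
#' @param hemisphere Optional `"left"`/`"right"`, one value or one per ROI.
#'
#' @return A data frame of class `"roiset"` with columns `name`, `lobe`,
#'   `subdomain`, `hemisphere`.
#' @export
#' @examples
#' roiset(c("SPL7A", "PMd1"), c("parietal", "premotor"))
roiset <- function(name, lobe, subdomain = NA_character_, hemisphere = NA_character_) {
  name <- as.character(name)
  lobe <- as.character(lobe)
  if (anyDuplicated(name)) {
    stop("ROI names must be unique; duplicated: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (length(lobe) != length(name)) {
    stop("'lobe' must have one entry per ROI")
  }
  bad <- setdiff(unique(lobe), c("parietal", "premotor"))
  if (length(bad)) {
    stop("unknown lobe label(s): ", paste(bad, collapse = ", "))
  }
  rs <- data.frame(
    name = name,
    lobe = lobe,
    subdomain = rep_len(as.character(subdomain), length(name)),
    hemisphere = rep_len(as.character(hemisphere), length(name)),
    stringsAsFactors = FALSE
  )
  class(rs) <- c("roiset", "data.frame")
  rs
}

#' Read an ROI metadata table
#'
#' Expects a CSV/TSV with at least columns `name` and `lobe`; `subdomain`
#' and `hemisphere` are carried through when present.
#'
#' @param path Path to the metadata table.
#' @return A [roiset()].
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) stop("ROI metadata file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("name", "lobe")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("ROI table misses column(s): ", paste(miss, collapse = ", "))
  roiset(
    dt$name, dt$lobe,
    subdomain = if ("subdomain" %in% names(dt)) dt$subdomain else NA_character_,
    hemisphere = if ("hemisphere" %in% names(dt)) dt$hemisphere else NA_character_
  )
}

#' The default 37-ROI parieto-premotor atlas configuration
#'
#' 23 parietal and 14 premotor/prefrontal areas per hemisphere, labelled
#' after cytoarchitectonic parcels commonly used for parieto-frontal
#' connectivity studies. The labels provide a realistic template for the
#' synthetic cohort generator; they are not tied to any particular dataset.
#'
#' @param hemisphere `"left"` or `"right"`.
#' @return A [roiset()] with 37 rows.
#' @export
default_roiset <- function(hemisphere = "left") {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  parietal <- data.frame(
    name = c("hIP1", "hIP2", "hIP3", "hIP4", "hIP5", "hIP6", "hIP7", "hIP8",
             "PF", "PFcm", "PFm", "PFop", "PFt", "PGa", "PGp",
             "5Ci", "5L", "5M", "7A", "7M", "7P", "7PC", "2"),
    subdomain = c(rep("aIPS", 3), rep("IPS", 5),
                  rep("IPL", 7),
                  rep("SPL", 7), "postcentral"),
    stringsAsFactors = FALSE
  )
  premotor <- data.frame(
    name = c("6d1", "6d2", "6d3", "6v1", "6v2", "PMv",
             "PreSMA", "SMAproper", "44", "45",
             "IFJ1", "IFJ2", "IFS1", "IFS4"),
    subdomain = c(rep("PMd", 3), rep("PMv", 3),
                  rep("SMA", 2), rep("IFG", 2),
                  rep("IFJ", 2), rep("IFS", 2)),
    stringsAsFactors = FALSE
  )
  roiset(
    name = c(parietal$name, premotor$name),
    lobe = c(rep("parietal", nrow(parietal)), rep("premotor", nrow(premotor))),
    subdomain = c(parietal$subdomain, premotor$subdomain),
    hemisphere = hemisphere
  )
}

#' @export
print.roiset <- function(x, ...) {
  cat(sprintf("<roiset> %d ROIs (%d parietal, %d premotor)\n",
              nrow(x), sum(x$lobe == "parietal"), sum(x$lobe == "premotor")))
  NextMethod()
}
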