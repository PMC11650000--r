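# 34 Desikan-Killiany cortical region names per hemisphere, ordered roughly
# anterior -> posterior so the index doubles as a posteriority coordinate for
# the default alpha amplitude topography.
.dk34 <- c(
  "frontalpole", "rostralanteriorcingulate", "medialorbitofrontal",
  "lateralorbitofrontal", "parsorbitalis", "rostralmiddlefrontal",
  "parstriangularis", "parsopercularis", "caudalanteriorcingulate",
  "superiorfrontal", "caudalmiddlefrontal", "insula", "precentral",
  "temporalpole", "entorhinal", "parahippocampal", "paracentral",
  "postcentral", "transversetemporal", "superiortemporal",
  "middletemporal", "inferiortemporal", "fusiform", "posteriorcingulate",
  "supramarginal", "isthmuscingulate", "bankssts", "superiorparietal",
  "inferiorparietal", "precuneus", "lingual", "pericalcarine", "cuneus",
  "lateraloccipital")

#' Default 68-region cortical parcellation
#'
#' The standard 68-region Desikan-Killiany-style cortical parcellation used
#' throughout the package: 34 regions per hemisphere, left-hemisphere block
#' first, each hemisphere ordered roughly anterior to posterior.  The
#' `weight` column is the default alpha amplitude topography: posterior
#' regions carry the strongest alpha (weight 1), tapering linearly to 0.4 at
#' the most anterior region, emulating the posterior-dominant eyes-closed
#' alpha rhythm.
#'
#' @param n_regions Total region count (even; default 68). Non-default
#'   counts keep the half/half hemisphere split and the linear taper but use
#'   generic labels.
#' @return A data.frame with columns `label`, `hemisphere` ("left"/"right")
#'   and `weight`.
#' @examples
#' head(dk68_parcellation())
#' @export
dk68_parcellation <- function(n_regions = 68L) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L || n_regions %% 2L != 0L)
    stop("n_regions must be an even count >= 2, got ", n_regions)
  nh <- n_regions %/% 2L
  if (nh == 34L) {
    labels <- c(paste0("lh_", .dk34), paste0("rh_", .dk34))
  } else {
    labels <- c(sprintf("lh_region%02d", seq_len(nh)),
                sprintf("rh_region%02d", seq_len(nh)))
  }
  # anterior (index 1) -> posterior (index nh); weight 0.4 -> 1.0
  w <- if (nh == 1L) 1 else 0.4 + 0.6 * (seq_len(nh) - 1) / (nh - 1)
  data.frame(label = labels,
             hemisphere = rep(c("left", "right"), each = nh),
             weight = rep(w, 2L),
             stringsAsFactors = FALSE)
}
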