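#' Load the packaged prognostic-signature fixtures
#'
#' The package ships, as plain-text fixtures under \code{extdata}, the
#' two published result tables of the study the pipeline reproduces:
#' nine gene-set classifiers with their DEG members and profile modes
#' (absolute cancer expression \code{C}, paired ratios \code{C/P} and
#' \code{P/N}, and the normal-referenced \code{C/N}), and the two
#' miRNA-substituted sets with their source DEG lists. Because the
#' publication lists miRNA substitutions only at the set level, the
#' packaged consensus map reproducing those relations is synthetic: it
#' assigns each listed miRNA to listed DEGs so the set-level
#' substitutions are reproduced exactly
#' (\code{table2_consensus_map_synthetic.tsv}).
#'
#' @return list with \code{table1} (data.frame: set, deg_group, profile,
#'   members list-column), \code{classifiers} (list of
#'   \code{\link{classifier}} objects, one per set/mode pair),
#'   \code{mirna_sets} (data.frame: set, deg_members and mirnas
#'   list-columns), \code{consensus_map} (synthetic
#'   \code{"consensus_map"} reproducing the printed relations).
#' @examples
#' fx <- load_fixtures()
#' length(fx$table1$members[[1]])   # chr1q32 has 9 members
#' @export
load_fixtures <- function() {
  ext <- function(f) {
    p <- system.file("extdata", f, package = "gradprog")
    .assert(nzchar(p), paste("missing packaged fixture:", f))
    p
  }
  t1 <- utils::read.delim(ext("table1_classifiers.tsv"),
                          stringsAsFactors = FALSE)
  .assert(all(c("set", "deg_group", "profile", "members") %in% names(t1)),
          "malformed table1 fixture")
  t1$members <- lapply(strsplit(t1$members, ","), trimws)
  .assert(nrow(t1) == 9, "table1 fixture must hold nine classifiers")

  clfs <- list()
  for (i in seq_len(nrow(t1))) {
    modes <- trimws(strsplit(t1$profile[i], "&")[[1]])
    for (m in modes) {
      id <- if (length(modes) > 1) paste0(t1$set[i], "|", m) else t1$set[i]
      clfs[[id]] <- classifier(t1$set[i], t1$members[[i]],
                               kind = "gene", mode = m)
    }
  }

  t2 <- utils::read.delim(ext("table2_mirna_sets.tsv"),
                          stringsAsFactors = FALSE)
  .assert(all(c("set", "deg_members", "mirnas") %in% names(t2)),
          "malformed table2 fixture")
  t2$deg_members <- lapply(strsplit(t2$deg_members, ","), trimws)
  t2$mirnas <- lapply(strsplit(t2$mirnas, ","), trimws)
  .assert(nrow(t2) == 2, "table2 fixture must hold two miRNA sets")

  map <- read_target_tsv(ext("table2_consensus_map_synthetic.tsv"))
  class(map) <- c("consensus_map", "data.frame")

  list(table1 = t1, classifiers = clfs, mirna_sets = t2,
       consensus_map = map)
}
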