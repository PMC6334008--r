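#' @include AllClasses.R
NULL

#' Load a packaged validation fixture
#'
#' Two gene-level summary tables ship with the package for validating the
#' fold-change arithmetic, the two-line DE partition and the pathway
#' down-regulation counts without any external data:
#' \describe{
#'   \item{table1}{35 differentially expressed heat shock protein (HSP)
#'     family genes with heat/control read counts and log2 fold changes per
#'     line (20 DE in both lines, 11 in the sensitive line RL only, 4 in the
#'     tolerant line YL only).  A unique \code{gene_id} is added because
#'     several distinct transcripts share an annotation name.}
#'   \item{table2}{12 differentially expressed cell cycle / DNA replication
#'     genes with per-line log2 fold changes (all down-regulated under
#'     heat).}
#' }
#'
#' @param name "table1" (alias "hsp") or "table2" (alias "cellcycle").
#' @param membership for table1, optionally restrict to "both", "RL_only" or
#'   "YL_only".
#' @return a data.frame (class \code{fixtureTable}).
#' @export
#' @examples
#' nrow(loadFixture("table1"))                        # 35
#' nrow(loadFixture("table1", membership = "both"))   # 20
loadFixture <- function(name, membership = NULL) {
  files <- c(table1 = "hsp_deg_table.tsv", hsp = "hsp_deg_table.tsv",
             table2 = "cellcycle_deg_table.tsv",
             cellcycle = "cellcycle_deg_table.tsv")
  if (!name %in% names(files))
    stop("unknown fixture '", name, "'; available: ",
         paste(unique(names(files)), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "abtseq",
                      mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  if (files[[name]] == "hsp_deg_table.tsv") {
    stopifnot(nrow(df) == 35)
    df$gene_id <- sprintf("hsp_%02d", seq_len(nrow(df)))
    rl <- !is.na(df$log2fc_RL); yl <- !is.na(df$log2fc_YL)
    stopifnot(all((df$membership == "both") == (rl & yl)),
              all((df$membership == "RL_only") == (rl & !yl)),
              all((df$membership == "YL_only") == (!rl & yl)))
    if (!is.null(membership)) {
      stopifnot(membership %in% c("both", "RL_only", "YL_only"))
      df <- df[df$membership == membership, , drop = FALSE]
    }
  } else {
    stopifnot(nrow(df) == 12, is.null(membership))
  }
  rownames(df) <- NULL
  class(df) <- c("fixtureTable", "data.frame")
  df
}

#' Recast a fixture table as per-line DE result tables
#'
#' Converts a packaged fixture into the (gene_id, log2_fc, de_flag,
#' direction) tables consumed by \code{\link{familySummary}},
#' \code{\link{pathwayUpDownCounts}} and \code{\link{vennPartition}}: a gene
#' is DE in a line iff the fixture prints a fold change for that line.
#'
#' @param fixture a \code{fixtureTable} from \code{\link{loadFixture}}.
#' @return list with elements \code{sensitive} (RL) and \code{tolerant}
#'   (YL), plus \code{families} (for table1) or \code{pathways} (for
#'   table2).
#' @export
fixtureContrasts <- function(fixture) {
  stopifnot(inherits(fixture, "fixtureTable"))
  mk <- function(lfc, gid) {
    de <- !is.na(lfc)
    data.frame(gene_id = gid, log2_fc = lfc, de_flag = de,
               direction = ifelse(!de, "ns",
                                  ifelse(lfc > 0, "up", "down")),
               row.names = NULL)
  }
  out <- list(sensitive = mk(fixture$log2fc_RL, fixture$gene_id),
              tolerant = mk(fixture$log2fc_YL, fixture$gene_id))
  if ("membership" %in% names(fixture)) {
    out$families <- data.frame(gene_id = fixture$gene_id, family = "HSP")
  } else {
    out$pathways <- data.frame(gene_id = fixture$gene_id,
                               pathway = fixture$pathway)
  }
  out
}
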