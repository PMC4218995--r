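#' @include AllClasses.R
NULL

# Parse one NCBI taxdump-dialect file: fields separated by "\t|\t",
# records terminated by "\t|".
parseDmp <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
}

# Compute depths by breadth-first traversal from the root and construct a
# validated tree. Nodes unreachable from the root (orphans or cycles) are a
# structure error.
newTaxonomyTree <- function(taxid, parent, rank, name) {
    taxid <- as.integer(taxid); parent <- as.integer(parent)
    if (anyDuplicated(taxid))
        stop("duplicated taxids: ",
             paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
    orphan <- setdiff(parent, taxid)
    if (length(orphan))
        stop("taxonomy structure error, parent taxids absent from nodes: ",
             paste(orphan, collapse = ", "))
    rootPos <- which(taxid == parent)
    if (length(rootPos) != 1)
        stop("taxonomy must have exactly one root (its own parent); found ",
             length(rootPos))
    depth <- rep(NA_integer_, length(taxid))
    depth[rootPos] <- 0L
    parentPos <- match(parent, taxid)
    frontier <- rootPos
    d <- 0L
    while (length(frontier)) {
        d <- d + 1L
        frontier <- which(parentPos %in% frontier & is.na(depth))
        depth[frontier] <- d
    }
    if (anyNA(depth))
        stop("taxonomy structure error, nodes unreachable from root (cycle?): ",
             paste(taxid[is.na(depth)], collapse = ", "))
    ord <- order(taxid)
    nodes <- data.frame(taxid = taxid[ord], parent = parent[ord],
                        rank = rank[ord], name = name[ord], depth = depth[ord],
                        stringsAsFactors = FALSE)
    new("TaxonomyTree", nodes = nodes, rootTaxid = taxid[rootPos])
}

#' Load a taxonomy tree from taxdump-dialect nodes/names files
#'
#' Reads the pipe-delimited `nodes.dmp` (taxid, parent taxid, rank) and
#' `names.dmp` (scientific names) dialect and computes every node's depth by
#' traversal from the root. The root is the node that is its own parent.
#'
#' @param nodesPath path to the nodes file.
#' @param namesPath path to the names file; rows whose name class is
#'   `"scientific name"` supply the node names (first name wins otherwise).
#' @return a [TaxonomyTree].
#' @export
loadTaxonomy <- function(nodesPath, namesPath) {
    nd <- parseDmp(nodesPath)
    taxid <- vapply(nd, `[`, "", 1)
    parent <- vapply(nd, `[`, "", 2)
    rank <- vapply(nd, function(x) if (length(x) >= 3) x[3] else "no rank", "")
    nm <- parseDmp(namesPath)
    ntax <- as.integer(vapply(nm, `[`, "", 1))
    nname <- vapply(nm, `[`, "", 2)
    nclass <- vapply(nm, function(x) if (length(x) >= 4) x[4] else "", "")
    pref <- order(nclass != "scientific name")   # scientific names first
    ntax <- ntax[pref]; nname <- nname[pref]
    name <- nname[match(as.integer(taxid), ntax)]
    name[is.na(name)] <- paste0("taxid:", taxid[is.na(name)])
    newTaxonomyTree(taxid, parent, rank, name)
}

#' Root-to-node lineage
#'
#' @param tree a [TaxonomyTree].
#' @param taxid a single taxid present in the tree.
#' @return integer vector starting at the root and ending at `taxid`;
#'   consecutive entries are parent to child.
#' @examples
#' fix <- makeReferenceFixture(nTaxa = 2, seed = 1)
#' lineage(fix$tree, fix$map@map[[1]])
#' @export
lineage <- function(tree, taxid) {
    stopifnot(is(tree, "TaxonomyTree"))
    idx <- match(as.integer(taxid), tree@nodes$taxid)
    if (length(taxid) != 1 || is.na(idx))
        stop("unknown taxid: ", taxid)
    path <- integer(tree@nodes$depth[idx] + 1L)
    k <- length(path)
    cur <- idx
    repeat {
        path[k] <- tree@nodes$taxid[cur]
        if (tree@nodes$taxid[cur] == tree@rootTaxid) break
        cur <- match(tree@nodes$parent[cur], tree@nodes$taxid)
        k <- k - 1L
    }
    path
}

#' Project taxids onto the slim at a given depth
#'
#' A node deeper than `depth` is reported through its ancestor at exactly
#' `depth`; a node at or above `depth` passes through unchanged. The result
#' always lies on the node's lineage, and the projection is idempotent.
#'
#' @param tree a [TaxonomyTree].
#' @param taxid integer vector of taxids (vectorized).
#' @param depth slim depth (>= 0); depth 0 maps everything to the root.
#' @return integer vector of projected taxids.
#' @export
slimProject <- function(tree, taxid, depth) {
    stopifnot(is(tree, "TaxonomyTree"), depth >= 0)
    taxid <- as.integer(taxid)
    if (!length(taxid)) return(integer(0))
    nd <- tree@nodes
    idx <- match(taxid, nd$taxid)
    if (anyNA(idx))
        stop("unknown taxid(s): ", paste(taxid[is.na(idx)], collapse = ", "))
    # hop every too-deep node to its parent until all are at <= depth
    repeat {
        deep <- which(nd$depth[idx] > depth)
        if (!length(deep)) break
        idx[deep] <- match(nd$parent[idx[deep]], nd$taxid)
    }
    nd$taxid[idx]
}

#' Load a subject-to-taxid mapping table
#'
#' Two-column tab-separated file (subject id, taxid), the dialect of NCBI
#' accession2taxid, used as the local, offline resolution of alignment
#' subjects to taxonomy nodes.
#'
#' @param path TSV file; lines starting with `#` are ignored.
#' @param tree optional [TaxonomyTree]; when given, every mapped taxid must
#'   exist in the tree (merged/deleted ids are not handled).
#' @return a [SubjectTaxMap].
#' @export
loadSubjectMap <- function(path, tree = NULL) {
    tb <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                     col.names = c("subject_id", "taxid"),
                     colClasses = c("character", "integer"))
    map <- setNames(tb$taxid, tb$subject_id)
    if (!is.null(tree)) {
        missing <- setdiff(map, taxIds(tree))
        if (length(missing))
            stop("mapped taxids absent from taxonomy: ",
                 paste(missing, collapse = ", "))
    }
    new("SubjectTaxMap", map = map)
}

#' Construct a SubjectTaxMap from vectors
#' @param subjectIds character vector of subject ids.
#' @param taxids integer vector of taxids, same length.
#' @return a [SubjectTaxMap].
#' @export
subjectTaxMap <- function(subjectIds, taxids) {
    new("SubjectTaxMap", map = setNames(as.integer(taxids), subjectIds))
}

#' Resolve alignment subjects to taxids
#'
#' Unmapped subjects resolve to the `NA` sentinel rather than erroring; the
#' census counts reads hitting such subjects as "unresolved".
#'
#' @param map a [SubjectTaxMap].
#' @param subjectIds character vector of subject ids.
#' @return integer vector of taxids with `NA` for unmapped subjects.
#' @export
resolveSubject <- function(map, subjectIds) {
    stopifnot(is(map, "SubjectTaxMap"))
    unname(map@map[match(subjectIds, names(map@map))])
}
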