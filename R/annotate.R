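## Host-genus habitat annotation of called phages.

#' Default habitat genus lists
#'
#' Editable configuration mapping predicted bacterial host genera to body
#' habitats. The vagina-associated list covers genera commonly found in
#' the vaginal tract (several of which are also gut inhabitants, hence the
#' dual-habitat flag in [annotateHosts()]); the gut list covers common
#' human gut inhabitants; the non-human list covers genera with no known
#' human habitat (environmental acidophiles, plant pathogens). Phages with
#' no host prediction inherit the habitat of their source database when
#' that database is gut-derived (`gutDatabases`).
#'
#' @param vagina,gut,nonHuman character vectors of genera.
#' @param gutDatabases databases whose sequences were mined from human gut
#'   samples.
#' @return a list of class `habitatGenusLists`.
#' @export
habitatGenusLists <- function(
        vagina = c("Streptococcus", "Megasphaera", "Prevotella",
                   "Bifidobacterium", "Roseburia", "Faecalibacterium",
                   "Clostridium", "Ruminococcus", "Lactobacillus"),
        gut = c("Escherichia", "Enterobacter", "Campylobacter",
                "Listeria", "Klebsiella"),
        nonHuman = c("Acidithiobacillus", "Dickeya"),
        gutDatabases = c("GPD", "GVD", "ELGV", "MGV")) {
    structure(list(vagina = vagina, gut = gut, nonHuman = nonHuman,
                   gutDatabases = gutDatabases),
              class = "habitatGenusLists")
}

classifyHabitat <- function(genus, database, lists) {
    gutDb <- database %in% lists$gutDatabases
    known <- !is.na(genus) & nzchar(genus)
    cls <- rep("unknown", length(genus))
    cls[!known & gutDb] <- "gut_associated"
    cls[known & gutDb] <- "gut_associated"   # fallback for unlisted genera
    cls[known & genus %in% lists$gut] <- "gut_associated"
    cls[known & genus %in% lists$nonHuman] <- "non_human_habitat"
    cls[known & genus %in% lists$vagina] <- "vagina_associated"
    dual <- known & genus %in% lists$vagina & genus %in% lists$gut
    list(class = cls, dual = dual)
}

#' Annotate called phages with host habitat classes
#'
#' Joins every phage with at least one call to the database metadata and
#' classifies its predicted host genus as `vagina_associated`,
#' `gut_associated`, `non_human_habitat` or `unknown`. Genera on both the
#' vagina and gut lists are reported as vagina-associated with
#' `dual_habitat = TRUE`. Phages without a host prediction are
#' gut-associated when their source database is gut-derived, otherwise
#' unknown. The classification is a pure function of (host genus, source
#' database, configuration).
#'
#' @param calls a [PhageCallSet-class].
#' @param db a [PhageDb-class] carrying metadata (see
#'   [addPhageMetadata()]).
#' @param lists a [habitatGenusLists()].
#' @param dropPrevalent drop prevalent-flagged phages.
#' @return a data.frame: `database`, `phage_id`, `host_genus`,
#'   `morphology`, `habitat_class`, `dual_habitat`.
#' @export
annotateHosts <- function(calls, db, lists = habitatGenusLists(),
                          dropPrevalent = FALSE) {
    h <- sampleCountHistogram(calls, dropPrevalent = dropPrevalent)
    rec <- as.data.frame(db@records)
    idx <- match(paste(h$database, h$phage_id, sep = "::"),
                 paste(rec$database, rec$phage_id, sep = "::"))
    genus <- rec$host_genus[idx]
    morph <- rec$morphology[idx]
    cl <- classifyHabitat(genus, h$database, lists)
    data.frame(database = h$database, phage_id = h$phage_id,
               host_genus = genus, morphology = morph,
               habitat_class = cl$class, dual_habitat = cl$dual,
               stringsAsFactors = FALSE)
}

#' Habitat class by sample role summary
#'
#' For each habitat class, the number of annotated phages and how their
#' carrying samples split over maternal-only, cord-only (fetal) and both
#' roles.
#'
#' @param annotations output of [annotateHosts()].
#' @param calls the matching [PhageCallSet-class].
#' @param samples a [SampleSheet-class].
#' @return a data.frame per habitat class with counts `n_phages`,
#'   `n_maternal_only`, `n_cord_only`, `n_both`.
#' @export
habitatSummary <- function(annotations, calls, samples) {
    if (!nrow(annotations))
        return(data.frame(habitat_class = character(0),
                          n_phages = integer(0), n_maternal_only = integer(0),
                          n_cord_only = integer(0), n_both = integer(0),
                          stringsAsFactors = FALSE))
    act <- as.data.frame(activeSamples(samples)@samples)
    called <- assay(calls, "called")
    roleOf <- act$role[match(colnames(calls), act$sample_id)]
    keys <- phageKeys(calls)
    annKey <- paste(annotations$database, annotations$phage_id, sep = "::")
    roleClass <- vapply(annKey, function(k) {
        i <- match(k, keys)
        carriers <- which(called[i, ] & !is.na(roleOf))
        r <- unique(roleOf[carriers])
        if (length(r) == 2L) "both"
        else if (identical(r, "maternal")) "maternal_only"
        else if (identical(r, "fetal")) "cord_only"
        else "none"
    }, "")
    classes <- sort(unique(annotations$habitat_class))
    out <- lapply(classes, function(cl) {
        sel <- annotations$habitat_class == cl
        data.frame(habitat_class = cl,
                   n_phages = sum(sel),
                   n_maternal_only = sum(sel & roleClass == "maternal_only"),
                   n_cord_only = sum(sel & roleClass == "cord_only"),
                   n_both = sum(sel & roleClass == "both"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
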