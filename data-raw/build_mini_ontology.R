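# Builds inst/extdata/mini_ontology.json, the packaged fixture terminology.
# Run from the package root:  Rscript data-raw/build_mini_ontology.R
# The JSON is committed; this script is the editable source of record.

pkgload::load_all(".", quiet = TRUE)

cl <- function(id, label, synonyms = character(), parents = character(),
               grading = NULL) {
  ann <- if (is.null(grading)) list() else list(grading_value = grading)
  list(id = id, label = label, synonyms = synonyms, parents = parents,
       annotations = ann)
}

classes <- list(
  # scaffolding
  cl("NeuropathologyEntity", "neuropathology entity"),
  cl("AnatomicalStructure", "anatomical structure", parents = "NeuropathologyEntity"),
  cl("PathologyFinding", "pathology finding", parents = "NeuropathologyEntity"),
  cl("Diagnosis", "diagnosis", parents = "NeuropathologyEntity"),
  cl("CellType", "cell type", parents = "NeuropathologyEntity"),
  cl("Epitope", "epitope", parents = "NeuropathologyEntity"),
  cl("ImagingFinding", "imaging finding", parents = "NeuropathologyEntity"),

  # anatomy
  cl("Hippocampus", "hippocampus", c("hippocampal formation", "cornu ammonis"),
     "AnatomicalStructure"),
  cl("CA1", "ca1", c("ca1 subfield", "sommer sector"), "Hippocampus"),
  cl("CA2", "ca2", c("ca2 subfield", "ca2 sector"), "Hippocampus"),
  cl("CA3", "ca3", c("ca3 subfield", "ca3 sector"), "Hippocampus"),
  cl("CA4", "ca4", c("ca4 subfield", "end folium"), "Hippocampus"),
  cl("DentateGyrus", "dentate gyrus", "fascia dentata", "Hippocampus"),
  cl("TemporalLobe", "temporal lobe", c("temporal cortex", "temporal neocortex"),
     "AnatomicalStructure"),
  cl("FrontalLobe", "frontal lobe", "frontal cortex", "AnatomicalStructure"),
  cl("ParietalLobe", "parietal lobe", "parietal cortex", "AnatomicalStructure"),
  cl("OccipitalLobe", "occipital lobe", "occipital cortex", "AnatomicalStructure"),
  cl("Amygdala", "amygdala", "amygdaloid body", "AnatomicalStructure"),
  cl("Neocortex", "neocortex", c("cerebral cortex", "isocortex"),
     "AnatomicalStructure"),
  cl("WhiteMatter", "white matter", "subcortical white matter",
     "AnatomicalStructure"),
  cl("PeriventricularRegion", "periventricular region", "periventricular zone",
     "AnatomicalStructure"),
  cl("Insula", "insula", "insular cortex", "AnatomicalStructure"),
  cl("Hypothalamus", "hypothalamus", character(), "AnatomicalStructure"),

  # cell types
  cl("Neuron", "neuron", "nerve cell", "CellType"),
  cl("GlialCell", "glial cell", "glia", "CellType"),
  cl("Astrocyte", "astrocyte", "astroglia", "GlialCell"),
  cl("Microglia", "microglia", "microglial cell", "GlialCell"),
  cl("Oligodendrocyte", "oligodendrocyte", character(), "GlialCell"),
  cl("GranuleCell", "granule cell", character(), "Neuron"),
  cl("BalloonCell", "balloon cell", "ballooned cell", "CellType"),
  cl("DysmorphicNeuron", "dysmorphic neuron", "abnormal neuronal morphology",
     "Neuron"),

  # microscopy findings
  cl("NeuronalLoss", "neuronal loss",
     c("neuronal cell loss", "depletion of neuron", "segmental cell loss",
       "reduced neuronal density", "loss of neurons", "pyramidal cell loss"),
     "PathologyFinding"),
  cl("ModerateNeuronalLoss", "moderate neuronal loss", character(),
     "NeuronalLoss", grading = 1),
  cl("SevereNeuronalLoss", "severe neuronal loss", character(),
     "NeuronalLoss", grading = 2),
  cl("Astrogliosis", "astrogliosis",
     c("astroglial scarring", "astrocytic gliosis", "reactive astrogliosis"),
     "PathologyFinding"),
  cl("ModerateAstrogliosis", "moderate astrogliosis", character(),
     "Astrogliosis", grading = 0),
  cl("FibrillaryAstrogliosis", "fibrillary astrogliosis", character(),
     "Astrogliosis", grading = 2),
  cl("GranuleCellDispersion", "granule cell dispersion",
     "dispersion of granule cells", "PathologyFinding", grading = 1),
  cl("SevereGranuleCellLoss", "severe granule cell loss", character(),
     "PathologyFinding", grading = 2),
  cl("Heterotopia", "heterotopia", c("heterotropia", "neuronal heterotopia"),
     "PathologyFinding"),
  cl("NodularHeterotopia", "nodular heterotopia",
     c("microglia nodules", "periventricular nodular heterotropia",
       "multinodular lesion",
       "heterotropic neuronal nodules at periventricular site",
       "bilateral periventricular heterotropia", "nodular heterotropia"),
     "Heterotopia"),
  cl("BandHeterotopia", "band heterotopia", "double cortex", "Heterotopia"),
  cl("CorticalDyslamination", "cortical dyslamination",
     c("dyslamination", "disrupted cortical layering",
       "loss of cortical lamination"),
     "PathologyFinding"),
  cl("Polymicrogyria", "polymicrogyria", "excessive small gyri",
     "PathologyFinding"),
  cl("Schizencephaly", "schizencephaly", character(), "PathologyFinding"),
  cl("PerivascularLymphocyticInfiltrate", "perivascular lymphocytic infiltrate",
     c("perivascular lymphocytes", "lymphocytic cuffing",
       "perivascular inflammation"),
     "PathologyFinding"),
  cl("MicroglialActivation", "microglial activation", "activated microglia",
     "PathologyFinding"),
  cl("Neuronophagia", "neuronophagia", character(), "PathologyFinding"),
  cl("HemosiderinDeposition", "hemosiderin deposition",
     c("hemosiderin deposits", "hemosiderin laden macrophages"),
     "PathologyFinding"),
  cl("VascularMalformationFinding", "vascular malformation",
     c("abnormal vascular channels", "dilated vascular spaces"),
     "PathologyFinding"),
  cl("NeurofibrillaryTangles", "neurofibrillary tangles", "tau tangles",
     "PathologyFinding"),
  cl("AmyloidPlaque", "amyloid plaques",
     c("amyloid beta plaques", "senile plaques"), "PathologyFinding"),
  cl("TumorCellInfiltration", "tumor cell infiltration",
     c("infiltrating tumor cells", "tumour infiltration"), "PathologyFinding"),
  cl("AstrocyticProliferation", "astrocytic proliferation",
     "proliferation of astrocytes", "PathologyFinding"),
  cl("Microcalcification", "microcalcification", "calcification",
     "PathologyFinding"),
  cl("RosenthalFibers", "rosenthal fibers", "rosenthal fibres",
     "PathologyFinding"),
  cl("MitoticFigures", "mitotic figures", c("mitoses", "mitotic activity"),
     "PathologyFinding"),
  cl("EpithelialLining", "epithelial lining",
     "cyst wall with epithelial lining", "PathologyFinding"),
  cl("PreservedNeurons", "preserved neuronal density",
     c("normal neuronal density", "no neuronal loss"), "PathologyFinding"),
  cl("NonspecificChanges", "nonspecific changes",
     c("mild nonspecific changes", "no specific pathology"),
     "PathologyFinding"),

  # immunohistochemistry epitopes
  cl("GFAP", "gfap",
     c("gfap positive", "gfap immunopositivity",
       "glial fibrillary acidic protein"), "Epitope"),
  cl("Vimentin", "vimentin", c("vimentin positive", "vimentin expression"),
     "Epitope"),
  cl("NeuN", "neun", c("neun positive", "neun immunostaining"), "Epitope"),
  cl("Ki67", "ki67", c("ki 67", "ki67 proliferation index", "mib 1"),
     "Epitope"),
  cl("CD34", "cd34", "cd34 positive", "Epitope"),
  cl("PhosphoS6", "phospho s6",
     c("phospho s6 ribosomal protein", "ps6 positive"), "Epitope"),
  cl("Synaptophysin", "synaptophysin", "synaptophysin positive", "Epitope"),
  cl("CD3", "cd3", "cd3 positive t cells", "Epitope"),
  cl("CD8", "cd8", "cd8 positive t cells", "Epitope"),
  cl("Tau", "tau", c("tau positive", "hyperphosphorylated tau"), "Epitope"),
  cl("IDH1", "idh1", c("idh1 mutant", "idh1 r132h"), "Epitope"),
  cl("MAP2", "map2", "map2 positive", "Epitope"),

  # imaging findings
  cl("HippocampalAtrophy", "hippocampal atrophy",
     c("atrophic hippocampus", "hippocampal volume loss"), "ImagingFinding"),
  cl("T2Hyperintensity", "t2 hyperintensity",
     c("t2 signal increase", "flair hyperintensity"), "ImagingFinding"),
  cl("CorticalThickening", "cortical thickening", "thickened cortex",
     "ImagingFinding"),
  cl("BlurredGrayWhiteJunction", "blurred gray white junction",
     c("blurring of the gray white matter junction",
       "indistinct gray white boundary"), "ImagingFinding"),
  cl("MassLesion", "mass lesion", c("space occupying lesion", "tumor mass"),
     "ImagingFinding"),
  cl("ContrastEnhancement", "contrast enhancement", "enhancing lesion",
     "ImagingFinding"),
  cl("CysticLesion", "cystic lesion", "cyst like lesion", "ImagingFinding"),
  cl("GeneralizedAtrophy", "generalized atrophy",
     c("global atrophy", "brain atrophy"), "ImagingFinding"),
  cl("FlowVoid", "flow voids", "serpentine flow voids", "ImagingFinding"),
  cl("NormalImaging", "unremarkable mri",
     c("normal mri", "no mri abnormality"), "ImagingFinding"),

  # diagnoses
  cl("HippocampalSclerosis", "hippocampal sclerosis",
     c("hs", "mesial temporal sclerosis"), "Diagnosis"),
  cl("HSType1", "hs ilae type 1",
     c("hippocampal sclerosis type 1", "hs type 1",
       "classical hippocampal sclerosis"), "HippocampalSclerosis"),
  cl("HSType2", "hs ilae type 2",
     c("hippocampal sclerosis type 2", "hs type 2"), "HippocampalSclerosis"),
  cl("HSType3", "hs ilae type 3",
     c("hippocampal sclerosis type 3", "hs type 3"), "HippocampalSclerosis"),
  cl("GliosisWithoutHS", "gliosis without hippocampal sclerosis",
     c("no hs", "gliosis only"), "Diagnosis"),
  cl("MalformationOfCorticalDevelopment", "malformation of cortical development",
     c("mcd", "cortical malformation"), "Diagnosis"),
  cl("FCDType1", "focal cortical dysplasia type 1",
     c("fcd type 1", "fcd i"), "MalformationOfCorticalDevelopment"),
  cl("FCDType2", "focal cortical dysplasia type 2",
     c("fcd type 2", "fcd ii"), "MalformationOfCorticalDevelopment"),
  cl("FCDType3", "focal cortical dysplasia type 3",
     c("fcd type 3", "fcd iii"), "MalformationOfCorticalDevelopment"),
  cl("BrainTumor", "brain tumor",
     c("brain tumour", "cerebral neoplasm", "brain neoplasm"), "Diagnosis"),
  cl("BrainGlialNeuronalTumor", "brain glial neuronal tumor",
     c("ganglioglioma", "glioneuronal tumor",
       "dysembryoplastic neuroepithelial tumor"), "BrainTumor"),
  cl("BrainGlialTumor", "brain glial tumor",
     c("glioma", "astrocytoma", "angiocentric glioma"), "BrainTumor"),
  cl("BrainNeuronalTumor", "brain neuronal tumor", "gangliocytoma",
     "BrainTumor"),
  cl("Hamartoma", "hamartoma", "hypothalamic hamartoma", "BrainTumor"),
  cl("EpithelialCyst", "epithelial cyst",
     c("epidermoid cyst", "colloid cyst", "cyst"), "BrainTumor"),
  cl("Meningioma", "meningioma", character(), "BrainTumor"),
  cl("MetastaticTumor", "metastatic tumor", c("metastasis", "secondary tumor"),
     "BrainTumor"),
  cl("Gliosis", "gliosis", c("reactive gliosis", "chronic gliosis"),
     "Diagnosis"),
  cl("Encephalitis", "encephalitis",
     c("chronic encephalitis", "rasmussen encephalitis", "limbic encephalitis"),
     "Diagnosis"),
  cl("Encephalopathy", "encephalopathy", "chronic encephalopathy", "Diagnosis"),
  cl("Cavernoma", "cavernoma", c("cavernous malformation", "cavernous angioma"),
     "Diagnosis"),
  cl("AlzheimersDisease", "alzheimer s disease",
     c("alzheimer disease", "ad pathology"), "Diagnosis"),
  cl("ArteriovenousMalformation", "arteriovenous malformation", "avm",
     "Diagnosis"),
  cl("DiagnosisNOS", "not otherwise specified",
     c("nos", "no definite diagnosis", "unclassified pathology"), "Diagnosis")
)

rel <- function(property, source, target, quantifier = "some") {
  data.frame(property = property, source = source, target = target,
             quantifier = quantifier, stringsAsFactors = FALSE)
}

relations <- rbind(
  rel("partOf", "CA1", "Hippocampus"),
  rel("partOf", "CA2", "Hippocampus"),
  rel("partOf", "CA3", "Hippocampus"),
  rel("partOf", "CA4", "Hippocampus"),
  rel("partOf", "DentateGyrus", "Hippocampus"),
  rel("partOf", "Hippocampus", "TemporalLobe"),
  rel("hasNeuroPathologyFinding", "HSType1", "NeuronalLoss"),
  rel("hasNeuroPathologyFinding", "HSType1", "Astrogliosis"),
  rel("hasAnatomicalLocation", "HSType1", "CA1"),
  rel("hasAnatomicalLocation", "HSType1", "CA4"),
  rel("hasNeuroPathologyFinding", "HSType2", "NeuronalLoss"),
  rel("hasAnatomicalLocation", "HSType2", "CA1"),
  rel("hasNeuroPathologyFinding", "HSType3", "NeuronalLoss"),
  rel("hasNeuroPathologyFinding", "HSType3", "Astrogliosis"),
  rel("hasAnatomicalLocation", "HSType3", "CA4"),
  rel("hasNeuroPathologyFinding", "GliosisWithoutHS", "Astrogliosis"),
  rel("hasNeuroPathologyFinding", "FCDType2", "BalloonCell"),
  rel("hasNeuroPathologyFinding", "FCDType2", "CorticalDyslamination"),
  rel("hasNeuroPathologyFinding", "FCDType3", "CorticalDyslamination"),
  rel("hasAdjacentLesion", "FCDType3", "VascularMalformationFinding"),
  rel("expressesEpitope", "BalloonCell", "Vimentin"),
  rel("expressesEpitope", "BalloonCell", "PhosphoS6"),
  rel("hasCellOrigin", "BrainGlialTumor", "Astrocyte"),
  rel("isCellOriginOf", "Astrocyte", "BrainGlialTumor"),
  rel("hasNeuroPathologyFinding", "Encephalitis",
      "PerivascularLymphocyticInfiltrate"),
  rel("hasNeuroPathologyFinding", "Cavernoma", "HemosiderinDeposition"),
  rel("hasNeuroPathologyFinding", "AlzheimersDisease", "NeurofibrillaryTangles"),
  rel("hasNeuroPathologyFinding", "AlzheimersDisease", "AmyloidPlaque")
)

compositions <- list(
  list(defined_class = "HSType1",
       components = data.frame(
         property = c("hasNeuroPathologyFinding", "hasAnatomicalLocation",
                      "hasAnatomicalLocation"),
         class = c("SevereNeuronalLoss", "CA1", "CA4"),
         stringsAsFactors = FALSE),
       connective = "AND"),
  list(defined_class = "HSType3",
       components = data.frame(
         property = c("hasNeuroPathologyFinding", "hasNeuroPathologyFinding",
                      "hasAnatomicalLocation"),
         class = c("SevereNeuronalLoss", "FibrillaryAstrogliosis", "CA4"),
         stringsAsFactors = FALSE),
       connective = "AND"),
  list(defined_class = "FCDType2",
       components = data.frame(
         property = c("hasNeuroPathologyFinding", "hasNeuroPathologyFinding"),
         class = c("CorticalDyslamination", "BalloonCell"),
         stringsAsFactors = FALSE),
       connective = "AND"),
  list(defined_class = "FCDType3",
       components = data.frame(
         property = c("hasNeuroPathologyFinding", "hasAdjacentLesion"),
         class = c("CorticalDyslamination", "VascularMalformationFinding"),
         stringsAsFactors = FALSE),
       connective = "AND"),
  list(defined_class = "GliosisWithoutHS",
       components = data.frame(
         property = c("hasNeuroPathologyFinding", "hasNeuroPathologyFinding"),
         class = c("Astrogliosis", "PreservedNeurons"),
         stringsAsFactors = FALSE),
       connective = "AND")
)

# Augment each class with regular plural/singular toggles of its surfaces so
# that number variation in reports stays inside the lexicon. Skip any toggle
# that would collide with a surface of another class.
all_keys <- new.env(parent = emptyenv())
for (i in seq_along(classes)) {
  for (s in c(classes[[i]]$label, classes[[i]]$synonyms)) {
    assign(ontofeat:::normalize_key(s), classes[[i]]$id, envir = all_keys)
  }
}
for (i in seq_along(classes)) {
  surfaces <- unique(c(classes[[i]]$label, classes[[i]]$synonyms))
  extra <- character()
  for (s in surfaces) {
    tog <- ontofeat:::plural_toggle(s)
    if (is.null(tog)) next
    key <- ontofeat:::normalize_key(tog)
    owner <- get0(key, envir = all_keys)
    if (is.null(owner)) {
      assign(key, classes[[i]]$id, envir = all_keys)
      extra <- c(extra, tog)
    } else if (!identical(owner, classes[[i]]$id)) {
      message(sprintf("skipping colliding plural '%s' (%s vs %s)",
                      tog, classes[[i]]$id, owner))
    }
  }
  classes[[i]]$synonyms <- unique(c(classes[[i]]$synonyms, extra))
}

# no normalized surface may be shared by two classes (mapping exactness)
keys <- ls(all_keys)
stopifnot(!anyDuplicated(keys))

ont <- ontology(classes, relations, compositions)
cat(sprintf("mini ontology: %d classes, %d relations, %d compositions\n",
            length(ont$classes), nrow(ont$relations), length(ont$compositions)))
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_lexicon(ont, "inst/extdata/mini_ontology.json")
cat("wrote inst/extdata/mini_ontology.json\n")
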