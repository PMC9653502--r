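# Diagnosis-conditioned concept model for the synthetic cohort generator.
#
# weights: cohort diagnosis counts (the published single-site case series);
# per-category maps give the inclusion probability of each canonical
# ontology concept in a patient's report, conditional on the diagnosis.
# Every diagnosis has at least one high-probability signature concept so
# the generated cohort is learnable. The true per-diagnosis finding
# frequencies of the source cohort are unpublished; these values are
# clinically plausible stand-ins, stated once and not tuned.

modifiers:
  - marked
  - focal
  - prominent
  - patchy
  - extensive
  - subtle
  - scattered
  - widespread
  - multifocal
  - pronounced
  - notable
  - distinct
  - apparent
  - evident
  - definite
  - conspicuous

# findings that may render as "finding in location" composites
locations:
  NeuronalLoss: [CA1, CA2, CA3, CA4, DentateGyrus]
  Astrogliosis: [CA1, CA2, CA3, CA4, Hippocampus]
  SevereNeuronalLoss: [CA1, CA4]
  GranuleCellDispersion: [DentateGyrus]
  SevereGranuleCellLoss: [DentateGyrus]
  CorticalDyslamination: [TemporalLobe, FrontalLobe]
  TumorCellInfiltration: [WhiteMatter, TemporalLobe]

diagnoses:
  HippocampalSclerosis:
    weight: 36
    microscopy:
      NeuronalLoss: 0.9
      Astrogliosis: 0.85
      GranuleCellDispersion: 0.35
      SevereNeuronalLoss: 0.3
    immunohistochemistry:
      NeuN: 0.7
      GFAP: 0.8
    imaging:
      HippocampalAtrophy: 0.9
      T2Hyperintensity: 0.5
    anatomy:
      Hippocampus: 0.9
      TemporalLobe: 0.6
      Amygdala: 0.15
  GliosisWithoutHS:
    weight: 10
    microscopy:
      Astrogliosis: 0.9
      PreservedNeurons: 0.85
    immunohistochemistry:
      GFAP: 0.9
      NeuN: 0.4
    imaging:
      NormalImaging: 0.6
      T2Hyperintensity: 0.3
    anatomy:
      Hippocampus: 0.8
      TemporalLobe: 0.5
  MalformationOfCorticalDevelopment:
    weight: 136
    microscopy:
      CorticalDyslamination: 0.85
      DysmorphicNeuron: 0.55
      BalloonCell: 0.4
      NodularHeterotopia: 0.25
      Polymicrogyria: 0.12
      BandHeterotopia: 0.08
    immunohistochemistry:
      Vimentin: 0.5
      PhosphoS6: 0.4
      NeuN: 0.45
      MAP2: 0.3
    imaging:
      BlurredGrayWhiteJunction: 0.7
      CorticalThickening: 0.6
      T2Hyperintensity: 0.35
    anatomy:
      FrontalLobe: 0.45
      TemporalLobe: 0.4
      Neocortex: 0.5
      PeriventricularRegion: 0.15
  BrainTumor:
    weight: 81
    microscopy:
      TumorCellInfiltration: 0.85
      AstrocyticProliferation: 0.55
      MitoticFigures: 0.5
      Microcalcification: 0.35
      RosenthalFibers: 0.2
    immunohistochemistry:
      Ki67: 0.75
      GFAP: 0.6
      CD34: 0.5
      Synaptophysin: 0.4
      IDH1: 0.25
    imaging:
      MassLesion: 0.9
      ContrastEnhancement: 0.55
      CysticLesion: 0.3
    anatomy:
      TemporalLobe: 0.6
      FrontalLobe: 0.3
      WhiteMatter: 0.3
  Gliosis:
    weight: 20
    microscopy:
      Astrogliosis: 0.9
      MicroglialActivation: 0.45
    immunohistochemistry:
      GFAP: 0.9
    imaging:
      T2Hyperintensity: 0.45
      NormalImaging: 0.3
    anatomy:
      WhiteMatter: 0.5
      TemporalLobe: 0.4
  Encephalitis:
    weight: 11
    microscopy:
      PerivascularLymphocyticInfiltrate: 0.9
      MicroglialActivation: 0.7
      Neuronophagia: 0.4
    immunohistochemistry:
      CD3: 0.85
      CD8: 0.6
    imaging:
      T2Hyperintensity: 0.6
    anatomy:
      TemporalLobe: 0.45
      Insula: 0.25
  EpithelialCyst:
    weight: 3
    microscopy:
      EpithelialLining: 0.9
    immunohistochemistry: {}
    imaging:
      CysticLesion: 0.9
    anatomy:
      TemporalLobe: 0.4
  Encephalopathy:
    weight: 2
    microscopy:
      NeuronalLoss: 0.5
      Astrogliosis: 0.6
      NonspecificChanges: 0.4
    immunohistochemistry: {}
    imaging:
      GeneralizedAtrophy: 0.8
    anatomy:
      Neocortex: 0.5
  Cavernoma:
    weight: 2
    microscopy:
      HemosiderinDeposition: 0.9
      VascularMalformationFinding: 0.8
    immunohistochemistry: {}
    imaging:
      MassLesion: 0.5
    anatomy:
      TemporalLobe: 0.4
  AlzheimersDisease:
    weight: 1
    microscopy:
      NeurofibrillaryTangles: 0.9
      AmyloidPlaque: 0.9
    immunohistochemistry:
      Tau: 0.9
    imaging:
      GeneralizedAtrophy: 0.7
    anatomy:
      Hippocampus: 0.5
  ArteriovenousMalformation:
    weight: 1
    microscopy:
      VascularMalformationFinding: 0.9
    immunohistochemistry: {}
    imaging:
      FlowVoid: 0.8
    anatomy:
      ParietalLobe: 0.4
  DiagnosisNOS:
    weight: 7
    microscopy:
      NonspecificChanges: 0.8
      Astrogliosis: 0.3
    immunohistochemistry: {}
    imaging:
      NormalImaging: 0.5
    anatomy:
      TemporalLobe: 0.3
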