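{
  "DefaultMode": ["MPFC", "LP (L)", "LP (R)", "PCC"],
  "SensoriMotor": ["Lateral (L)", "Lateral (R)", "Superior"],
  "Visual": ["Medial", "Occipital", "Lateral (L)", "Lateral (R)"],
  "Salience": ["ACC", "AInsula (L)", "AInsula (R)", "RPFC (L)", "RPFC (R)", "SMG (L)", "SMG (R)"],
  "DorsalAttention": ["FEF (L)", "FEF (R)", "IPS (L)", "IPS (R)"],
  "FrontoParietal": ["LPFC (L)", "LPFC (R)", "PPC (L)", "PPC (R)"],
  "Language": ["IFG (L)", "IFG (R)", "pSTG (L)", "pSTG (R)"],
  "Cerebellar": ["Anterior", "Posterior"],
  "Cortical": ["Frontal Pole (L)", "Frontal Pole (R)", "Insular Cortex (L)", "Insular Cortex (R)", "Superior Frontal Gyrus (L)", "Superior Frontal Gyrus (R)", "Middle Frontal Gyrus (L)", "Middle Frontal Gyrus (R)", "Inferior Frontal Gyrus pars triangularis (L)", "Inferior Frontal Gyrus pars triangularis (R)", "Inferior Frontal Gyrus pars opercularis (L)", "Inferior Frontal Gyrus pars opercularis (R)", "Precentral Gyrus (L)", "Precentral Gyrus (R)", "Temporal Pole (L)", "Temporal Pole (R)", "Superior Temporal Gyrus anterior (L)", "Superior Temporal Gyrus anterior (R)", "Superior Temporal Gyrus posterior (L)", "Superior Temporal Gyrus posterior (R)", "Middle Temporal Gyrus anterior (L)", "Middle Temporal Gyrus anterior (R)", "Middle Temporal Gyrus posterior (L)", "Middle Temporal Gyrus posterior (R)", "Middle Temporal Gyrus temporooccipital (L)", "Middle Temporal Gyrus temporooccipital (R)", "Inferior Temporal Gyrus anterior (L)", "Inferior Temporal Gyrus anterior (R)", "Inferior Temporal Gyrus posterior (L)", "Inferior Temporal Gyrus posterior (R)", "Inferior Temporal Gyrus temporooccipital (L)", "Inferior Temporal Gyrus temporooccipital (R)", "Postcentral Gyrus (L)", "Postcentral Gyrus (R)", "Superior Parietal Lobule (L)", "Superior Parietal Lobule (R)", "Supramarginal Gyrus anterior (L)", "Supramarginal Gyrus anterior (R)", "Supramarginal Gyrus posterior (L)", "Supramarginal Gyrus posterior (R)", "Angular Gyrus (L)", "Angular Gyrus (R)", "Lateral Occipital Cortex superior (L)", "Lateral Occipital Cortex superior (R)", "Lateral Occipital Cortex inferior (L)", "Lateral Occipital Cortex inferior (R)", "Intracalcarine Cortex (L)", "Intracalcarine Cortex (R)", "Frontal Medial Cortex (L)", "Frontal Medial Cortex (R)", "Juxtapositional Lobule (L)", "Juxtapositional Lobule (R)", "Subcallosal Cortex (L)", "Subcallosal Cortex (R)", "Paracingulate Gyrus (L)", "Paracingulate Gyrus (R)", "Cingulate Gyrus anterior (L)", "Cingulate Gyrus anterior (R)", "Cingulate Gyrus posterior (L)", "Cingulate Gyrus posterior (R)", "Precuneous Cortex (L)", "Precuneous Cortex (R)", "Cuneal Cortex (L)", "Cuneal Cortex (R)", "Frontal Orbital Cortex (L)", "Frontal Orbital Cortex (R)", "Parahippocampal Gyrus anterior (L)", "Parahippocampal Gyrus anterior (R)", "Parahippocampal Gyrus posterior (L)", "Parahippocampal Gyrus posterior (R)", "Lingual Gyrus (L)", "Lingual Gyrus (R)", "Temporal Fusiform Cortex anterior (L)", "Temporal Fusiform Cortex anterior (R)", "Temporal Fusiform Cortex posterior (L)", "Temporal Fusiform Cortex posterior (R)", "Temporal Occipital Fusiform Cortex (L)", "Temporal Occipital Fusiform Cortex (R)", "Occipital Fusiform Gyrus (L)", "Occipital Fusiform Gyrus (R)", "Frontal Operculum Cortex (L)", "Frontal Operculum Cortex (R)", "Central Opercular Cortex (L)", "Central Opercular Cortex (R)", "Parietal Operculum Cortex (L)", "Parietal Operculum Cortex (R)", "Planum Polare (L)", "Planum Polare (R)", "Heschls Gyrus (L)", "Heschls Gyrus (R)", "Planum Temporale (L)", "Planum Temporale (R)", "Supracalcarine Cortex (L)", "Supracalcarine Cortex (R)", "Occipital Pole (L)", "Occipital Pole (R)"],
  "Subcortical": ["Thalamus (L)", "Thalamus (R)", "Caudate (L)", "Caudate (R)", "Putamen (L)", "Putamen (R)", "Pallidum (L)", "Pallidum (R)", "Hippocampus (L)", "Hippocampus (R)", "Amygdala (L)", "Amygdala (R)", "Accumbens (L)", "Accumbens (R)", "Cerebral White Matter (L)", "Cerebral White Matter (R)", "Cerebral Cortex (L)", "Cerebral Cortex (R)", "Lateral Ventricle (L)", "Lateral Ventricle (R)"],
  "Cerebellum": ["Crus I (L)", "Crus I (R)", "Crus II (L)", "Crus II (R)", "Lobule III (L)", "Lobule III (R)", "Lobule IV V (L)", "Lobule IV V (R)", "Lobule VI (L)", "Lobule VI (R)", "Lobule VIIb (L)", "Lobule VIIb (R)", "Lobule VIII (L)", "Lobule VIII (R)", "Lobule IX (L)", "Lobule IX (R)"]
}
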