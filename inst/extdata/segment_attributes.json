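{
  "BodyPartExamined": "PELVIS",
  "ContentCreatorName": "ctqv",
  "SeriesDescription": "Segmentation",
  "SegmentAttributes": [
    [
      {
        "labelID": 1,
        "SegmentLabel": "pelvic hematoma",
        "SegmentAlgorithmType": "AUTOMATIC",
        "SegmentAlgorithmName": "threshold_stub",
        "SegmentedPropertyCategoryCodeSequence": {
          "CodeValue": "M-01000",
          "CodingSchemeDesignator": "SRT",
          "CodeMeaning": "Morphologically Altered Structure"
        },
        "SegmentedPropertyTypeCodeSequence": {
          "CodeValue": "M-35000",
          "CodingSchemeDesignator": "SRT",
          "CodeMeaning": "Hemorrhage"
        },
        "recommendedDisplayRGBValue": [216, 38, 38]
      }
    ]
  ]
}
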