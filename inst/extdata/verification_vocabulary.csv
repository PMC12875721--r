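code,name,group
Light,Light microscopy,microscopy
Phase,Phase contrast microscopy,microscopy
Confo,Confocal microscopy,microscopy
Elect,Electron microscopy,microscopy
Epifl,Epifluorescence microscopy,microscopy
DICmi,Differential interference contrast microscopy,microscopy
Plate,Agar plate counting,counting
FlowC,Flow cytometry,counting
Seq16,16S/18S sequencing,sequencing
AbSen,Antibiotic sensitivity,physiology
Absor,Absorbance,physiology
FlgSn,Flagella staining,physiology
GrStn,Gram staining,physiology
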