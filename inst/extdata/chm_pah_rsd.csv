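herb,part,Naph,Acy,Ace,Flu,Phe,Ant,Flt,Pyr,BaA,Chry,BbF,bkF,BaP,Ind(cd)P,DahA,BghiP
glycyrrhizae,root_stem,0.39,0.73,0.10,0.21,0.05,0.07,0.26,0.23,0.39,0.12,0.08,nd,nd,nd,nd,nd
honeysuckle,flower,0.25,0.32,0.56,0.51,0.21,nd,0.17,0.22,nd,0.21,0.08,nd,0.24,nd,nd,nd
coix_lacryma,fruit_seed,0.36,0.37,0.50,nd,0.58,0.29,0.83,nd,nd,nd,nd,nd,nd,nd,nd,nd
ginseng,root_stem,0.59,nd,0.47,nd,0.22,0.29,0.76,0.83,nd,nd,nd,nd,nd,nd,nd,nd
lotus_seed,fruit_seed,0.40,0.55,0.52,nd,0.30,0.23,0.64,0.21,nd,nd,nd,0.48,nd,nd,nd,nd
sterculia_lychnophora,fruit_seed,0.26,0.38,0.39,0.37,0.12,0.15,0.25,0.40,nd,nd,0.04,nd,nd,nd,nd,nd
lycium_chinense,fruit_seed,0.31,0.32,0.12,0.40,0.18,nd,nd,0.19,nd,nd,nd,nd,nd,nd,nd,nd
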