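synonym,ingredient,is_target_ici,ici_class
PEMBROLIZUMAB,PEMBROLIZUMAB,TRUE,PD1
KEYTRUDA,PEMBROLIZUMAB,TRUE,PD1
MK-3475,PEMBROLIZUMAB,TRUE,PD1
PEMBROLIZUMB,PEMBROLIZUMAB,TRUE,PD1
LAMBROLIZUMAB,PEMBROLIZUMAB,TRUE,PD1
NIVOLUMAB,NIVOLUMAB,TRUE,PD1
OPDIVO,NIVOLUMAB,TRUE,PD1
ONO-4538,NIVOLUMAB,TRUE,PD1
BMS-936558,NIVOLUMAB,TRUE,PD1
NIVOLUMUB,NIVOLUMAB,TRUE,PD1
TORIPALIMAB,TORIPALIMAB,TRUE,PD1
LOQTORZI,TORIPALIMAB,TRUE,PD1
JS001,TORIPALIMAB,TRUE,PD1
TUOYI,TORIPALIMAB,TRUE,PD1
TISLELIZUMAB,TISLELIZUMAB,TRUE,PD1
TEVIMBRA,TISLELIZUMAB,TRUE,PD1
BGB-A317,TISLELIZUMAB,TRUE,PD1
CEMIPLIMAB,CEMIPLIMAB,TRUE,PD1
CEMIPLIMAB-RWLC,CEMIPLIMAB,TRUE,PD1
LIBTAYO,CEMIPLIMAB,TRUE,PD1
REGN2810,CEMIPLIMAB,TRUE,PD1
DOSTARLIMAB,DOSTARLIMAB,TRUE,PD1
DOSTARLIMAB-GXLY,DOSTARLIMAB,TRUE,PD1
JEMPERLI,DOSTARLIMAB,TRUE,PD1
TSR-042,DOSTARLIMAB,TRUE,PD1
ATEZOLIZUMAB,ATEZOLIZUMAB,TRUE,PDL1
TECENTRIQ,ATEZOLIZUMAB,TRUE,PDL1
MPDL3280A,ATEZOLIZUMAB,TRUE,PDL1
ATEZOLIZUMB,ATEZOLIZUMAB,TRUE,PDL1
AVELUMAB,AVELUMAB,TRUE,PDL1
BAVENCIO,AVELUMAB,TRUE,PDL1
MSB0010718C,AVELUMAB,TRUE,PDL1
DURVALUMAB,DURVALUMAB,TRUE,PDL1
IMFINZI,DURVALUMAB,TRUE,PDL1
MEDI4736,DURVALUMAB,TRUE,PDL1
DURVALUMUB,DURVALUMAB,TRUE,PDL1
IPILIMUMAB,IPILIMUMAB,TRUE,CTLA4
YERVOY,IPILIMUMAB,TRUE,CTLA4
MDX-010,IPILIMUMAB,TRUE,CTLA4
IPILIMUMUB,IPILIMUMAB,TRUE,CTLA4
PACLITAXEL,PACLITAXEL,FALSE,
TAXOL,PACLITAXEL,FALSE,
PACLITAXEL PROTEIN-BOUND,PACLITAXEL,FALSE,
ABRAXANE,PACLITAXEL,FALSE,
CARBOPLATIN,CARBOPLATIN,FALSE,
PARAPLATIN,CARBOPLATIN,FALSE,
CISPLATIN,CISPLATIN,FALSE,
PLATINOL,CISPLATIN,FALSE,
ETOPOSIDE,ETOPOSIDE,FALSE,
VEPESID,ETOPOSIDE,FALSE,
ETOPOPHOS,ETOPOSIDE,FALSE,
CABOZANTINIB,CABOZANTINIB,FALSE,
CABOMETYX,CABOZANTINIB,FALSE,
AXITINIB,AXITINIB,FALSE,
INLYTA,AXITINIB,FALSE,
LEVOTHYROXINE,LEVOTHYROXINE,FALSE,
SYNTHROID,LEVOTHYROXINE,FALSE,
LEVOTHYROXINE SODIUM,LEVOTHYROXINE,FALSE,
LENVATINIB,LENVATINIB,FALSE,
LENVIMA,LENVATINIB,FALSE,
BEVACIZUMAB,BEVACIZUMAB,FALSE,
AVASTIN,BEVACIZUMAB,FALSE,
PEMETREXED,PEMETREXED,FALSE,
ALIMTA,PEMETREXED,FALSE,
GEMCITABINE,GEMCITABINE,FALSE,
GEMZAR,GEMCITABINE,FALSE,
OMEPRAZOLE,OMEPRAZOLE,FALSE,
PRILOSEC,OMEPRAZOLE,FALSE,
PANTOPRAZOLE,PANTOPRAZOLE,FALSE,
PROTONIX,PANTOPRAZOLE,FALSE,
METFORMIN,METFORMIN,FALSE,
GLUCOPHAGE,METFORMIN,FALSE,
METFORMIN HYDROCHLORIDE,METFORMIN,FALSE,
ASPIRIN,ASPIRIN,FALSE,
ACETYLSALICYLIC ACID,ASPIRIN,FALSE,
ATORVASTATIN,ATORVASTATIN,FALSE,
LIPITOR,ATORVASTATIN,FALSE,
PREDNISONE,PREDNISONE,FALSE,
DELTASONE,PREDNISONE,FALSE,
DEXAMETHASONE,DEXAMETHASONE,FALSE,
DECADRON,DEXAMETHASONE,FALSE,
FUROSEMIDE,FUROSEMIDE,FALSE,
LASIX,FUROSEMIDE,FALSE,
AMLODIPINE,AMLODIPINE,FALSE,
NORVASC,AMLODIPINE,FALSE,
AMLODIPINE BESYLATE,AMLODIPINE,FALSE,
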