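pt,hlgt,soc
Neuropathy peripheral,Peripheral neuropathies,Nervous system disorders
Peripheral sensory neuropathy,Peripheral neuropathies,Nervous system disorders
Peripheral motor neuropathy,Peripheral neuropathies,Nervous system disorders
Polyneuropathy,Peripheral neuropathies,Nervous system disorders
Guillain-Barre syndrome,Peripheral neuropathies,Nervous system disorders
Immune-mediated neuropathy,Peripheral neuropathies,Nervous system disorders
Chronic inflammatory demyelinating polyradiculoneuropathy,Peripheral neuropathies,Nervous system disorders
Neuralgia,Peripheral neuropathies,Nervous system disorders
Peroneal nerve palsy,Peripheral neuropathies,Nervous system disorders
Axonal neuropathy,Peripheral neuropathies,Nervous system disorders
Myasthenia gravis,Neuromuscular disorders,Nervous system disorders
Immune-mediated myasthenia gravis,Neuromuscular disorders,Nervous system disorders
Lambert-Eaton myasthenic syndrome,Neuromuscular disorders,Nervous system disorders
Myasthenic syndrome,Neuromuscular disorders,Nervous system disorders
Muscular weakness conditions,Neuromuscular disorders,Nervous system disorders
Encephalitis,Central nervous system infections and inflammations,Nervous system disorders
Immune-mediated encephalitis,Central nervous system infections and inflammations,Nervous system disorders
Autoimmune encephalitis,Central nervous system infections and inflammations,Nervous system disorders
Meningitis,Central nervous system infections and inflammations,Nervous system disorders
Meningitis aseptic,Central nervous system infections and inflammations,Nervous system disorders
Encephalomyelitis,Central nervous system infections and inflammations,Nervous system disorders
Paraneoplastic encephalomyelitis,Central nervous system infections and inflammations,Nervous system disorders
Meningoencephalitis,Central nervous system infections and inflammations,Nervous system disorders
Myelitis,Central nervous system infections and inflammations,Nervous system disorders
Myelitis transverse,Central nervous system infections and inflammations,Nervous system disorders
Meningoradiculitis,Central nervous system infections and inflammations,Nervous system disorders
Encephalopathy,Neurological disorders NEC,Nervous system disorders
Immune-mediated encephalopathy,Neurological disorders NEC,Nervous system disorders
Toxic encephalopathy,Neurological disorders NEC,Nervous system disorders
Immune-mediated neurological disorder,Neurological disorders NEC,Nervous system disorders
Paraneoplastic neurological syndrome,Neurological disorders NEC,Nervous system disorders
Neurotoxicity,Neurological disorders NEC,Nervous system disorders
Altered state of consciousness,Neurological disorders NEC,Nervous system disorders
Loss of consciousness,Neurological disorders NEC,Nervous system disorders
Syncope,Neurological disorders NEC,Nervous system disorders
Dizziness,Neurological disorders NEC,Nervous system disorders
Somnolence,Neurological disorders NEC,Nervous system disorders
Hypoaesthesia,Neurological disorders NEC,Nervous system disorders
Paraesthesia,Neurological disorders NEC,Nervous system disorders
Taste disorder,Neurological disorders NEC,Nervous system disorders
Dysgeusia,Neurological disorders NEC,Nervous system disorders
Ageusia,Neurological disorders NEC,Nervous system disorders
Aphasia,Neurological disorders NEC,Nervous system disorders
Dysarthria,Neurological disorders NEC,Nervous system disorders
Cerebral infarction,Central nervous system vascular disorders,Nervous system disorders
Cerebrovascular accident,Central nervous system vascular disorders,Nervous system disorders
Ischaemic stroke,Central nervous system vascular disorders,Nervous system disorders
Haemorrhage intracranial,Central nervous system vascular disorders,Nervous system disorders
Cerebral haemorrhage,Central nervous system vascular disorders,Nervous system disorders
Tremor,Movement disorders (incl parkinsonism),Nervous system disorders
Parkinsonism,Movement disorders (incl parkinsonism),Nervous system disorders
Dyskinesia,Movement disorders (incl parkinsonism),Nervous system disorders
Seizure,Seizures (incl subtypes),Nervous system disorders
Status epilepticus,Seizures (incl subtypes),Nervous system disorders
Generalised tonic-clonic seizure,Seizures (incl subtypes),Nervous system disorders
Multiple sclerosis,Demyelinating disorders,Nervous system disorders
Demyelination,Demyelinating disorders,Nervous system disorders
Optic neuritis,Neurological disorders of the eye,Nervous system disorders
Immune-mediated optic neuritis,Neurological disorders of the eye,Nervous system disorders
Headache,Headaches,Nervous system disorders
Migraine,Headaches,Nervous system disorders
Memory impairment,Mental impairment disorders,Nervous system disorders
Cognitive disorder,Mental impairment disorders,Nervous system disorders
Radiculopathy,Spinal cord and nerve root disorders,Nervous system disorders
Myelopathy,Spinal cord and nerve root disorders,Nervous system disorders
Cauda equina syndrome,Spinal cord and nerve root disorders,Nervous system disorders
Nausea,Gastrointestinal motility and defaecation conditions,Gastrointestinal disorders
Vomiting,Gastrointestinal motility and defaecation conditions,Gastrointestinal disorders
Diarrhoea,Gastrointestinal motility and defaecation conditions,Gastrointestinal disorders
Colitis,Gastrointestinal inflammatory conditions,Gastrointestinal disorders
Immune-mediated colitis,Gastrointestinal inflammatory conditions,Gastrointestinal disorders
Rash,Epidermal and dermal conditions,Skin and subcutaneous tissue disorders
Pruritus,Epidermal and dermal conditions,Skin and subcutaneous tissue disorders
Vitiligo,Pigmentation disorders,Skin and subcutaneous tissue disorders
Fatigue,General system disorders NEC,General disorders and administration site conditions
Asthenia,General system disorders NEC,General disorders and administration site conditions
Pyrexia,Body temperature conditions,General disorders and administration site conditions
Death,Fatal outcomes,General disorders and administration site conditions
Hypothyroidism,Thyroid gland disorders,Endocrine disorders
Hyperthyroidism,Thyroid gland disorders,Endocrine disorders
Thyroiditis,Thyroid gland disorders,Endocrine disorders
Adrenal insufficiency,Adrenal gland disorders,Endocrine disorders
Pneumonitis,Lower respiratory tract disorders,"Respiratory, thoracic and mediastinal disorders"
Dyspnoea,Respiratory disorders NEC,"Respiratory, thoracic and mediastinal disorders"
Cough,Respiratory disorders NEC,"Respiratory, thoracic and mediastinal disorders"
Hepatitis,Hepatic and hepatobiliary disorders,Hepatobiliary disorders
Immune-mediated hepatitis,Hepatic and hepatobiliary disorders,Hepatobiliary disorders
Acute kidney injury,Renal disorders,Renal and urinary disorders
Anaemia,Anaemias nonhaemolytic and marrow depression,Blood and lymphatic system disorders
Thrombocytopenia,"Platelet disorders",Blood and lymphatic system disorders
Neutropenia,White blood cell disorders,Blood and lymphatic system disorders
Arthralgia,Joint disorders,Musculoskeletal and connective tissue disorders
Myalgia,Muscle disorders,Musculoskeletal and connective tissue disorders
Myositis,Muscle disorders,Musculoskeletal and connective tissue disorders
Immune-mediated myositis,Muscle disorders,Musculoskeletal and connective tissue disorders
Decreased appetite,Appetite and general nutritional disorders,Metabolism and nutrition disorders
Diabetic ketoacidosis,Glucose metabolism disorders (incl diabetes mellitus),Metabolism and nutrition disorders
Malignant neoplasm progression,"Neoplasms malignant site unspecified NEC","Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Infusion related reaction,"Administration site reactions","Injury, poisoning and procedural complications"
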