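intraparenchymal hemorrhage	INTRAPARENCHYMAL HEMORRHAGE	intraparenchymal\s+(hemorrhages?|hematomas?)	
facial fracture	FACIAL FRACTURE	(facial|nasal|orbital)\s+(bone\s+)?fractures?	
extraaxial fluid collection	EXTRAAXIAL FLUID COLLECTION	extra-?axial\s+(fluid\s+)?collections?	
subdural hygroma	EXTRAAXIAL FLUID COLLECTION	subdural\s+hygromas?	
hypodensities	HYPODENSITIES	hypodensit(y|ies)|hypoattenuation	
skull fracture	SKULL FRACTURE	(skull|calvarial|temporal\s+bone|occipital\s+bone|parietal\s+bone|frontal\s+bone)\s+fractures?	
intraventricular hemorrhage	INTRAVENTRICULAR HEMORRHAGE	intraventricular\s+(hemorrhages?|blood|extension)	
herniation	HERNIATION	herniations?	
mass effect	MASS EFFECT	mass\s+effect	
subarachnoid hemorrhage	SUBARACHNOID HEMORRHAGE	subarachnoid\s+(hemorrhages?|blood)	
subdural hemorrhage	SUBDURAL HEMORRHAGE	subdural\s+(hemorrhages?|hematomas?|blood)	
hyperdensities	HYPERDENSITIES	hyperdensit(y|ies)|hyperattenuation	
atrophy	ATROPHY	atrophy	
volume loss	ATROPHY	volume\s+loss	
contusion	CONTUSION	contusions?	
hemorrhage	HEMORRHAGE	hemorrhages?|hematomas?	
intracranial hemorrhage	HEMORRHAGE	intracranial\s+(hemorrhages?|hematomas?)	
swelling	SWELLING	(brain\s+)?swelling	
pneumocephalus	PNEUMOCEPHALUS	pneumocephalus	
ischemia	ISCHEMIA	ischemias?|ischemic\s+changes?	
epidural hemorrhage	EPIDURAL HEMORRHAGE	epidural\s+(hemorrhages?|hematomas?|blood)	
anoxic	ANOXIC	anoxic(\s+(brain\s+)?injury)?|anoxia	
aneurysm	ANEURYSM	aneurysms?	
hydrocephalus	HYDROCEPHALUS	hydrocephalus|ventriculomegaly	
intracranial pathology	INTRACRANIAL PATHOLOGY	intracranial\s+patholog(y|ies)|acute\s+intracranial\s+(abnormalit(y|ies)|process|findings?)	
gray-white differentiation	GRAY-WHITE DIFFERENTIATION	gr[ae]y-?\s?white\s+(matter\s+)?differentiation	
cistern	CISTERN	(basal\s+|basilar\s+|suprasellar\s+|perimesencephalic\s+)?cisterns?	
midline shift	MIDLINE SHIFT	midline\s+shift	
diffuse axonal injury	DIFFUSE AXONAL INJURY	diffuse\s+axonal\s+injur(y|ies)	
microhemorrhage	MICROHEMORRHAGE	microhemorrhage(s)?	
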