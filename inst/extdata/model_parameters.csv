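# provenance: reference (published probability and cost estimates; blank se = fixed parameter)
name,description,mean,se,source
pDeath,Probability of death from ESS,0.0001,0.0003,published estimate
pIntraOpComp,Probability of intraoperative complication,0.0095,0.0004,published estimate
pNoIntraOpComp,Probability of no intraoperative complication,0.9904,0.0004,published estimate
pNoPostOpComp,Probability of no postoperative complication,0.8273,0.0069,published estimate
pPostOpComp,Probability of postoperative complication,0.1727,0.0069,published estimate
pPostOpInfection,Probability of postoperative infection (given a postoperative complication),0.647,0.047,published estimate
pPostOpEpistaxis,Probability of postoperative epistaxis (given a postoperative complication),0.352,0.047,published estimate
pPostOpCSFleak,Probability of postoperative CSF leak (given a postoperative complication),0.001,0.0002,published estimate
pPostOpEpistaxisCons,Probability of epistaxis resolving with conservative management,0.27,0.069,published estimate
pPostOpEpistaxisOR,Probability of epistaxis requiring OR management,0.73,0.069,published estimate
pPostOpCSFleakCons,Probability of CSF leak resolving with conservative management,0.19,0.054,published estimate
pPostOpCSFleakOR,Probability of CSF leak requiring OR management,0.81,0.054,published estimate
pRevisionESS,Probability of revision ESS per year,0.041,0.005,published estimate
cDeath,Cost of death,22548,,published estimate
cESS,Cost of ESS,10500,,published estimate
cMedical,Annual cost of medical treatment for CRS,772,,published estimate
cESSMajorComp,Incremental cost of major intraoperative complication,8354,,published estimate
cInfection,Cost of postoperative infection,559,,published estimate
cBleedCons,Cost of minor (conservatively managed) epistaxis,599,,published estimate
cBleedOR,Cost of major (OR-managed) epistaxis,6450,,published estimate
cCSFCons,Cost of self-limited CSF leak,13594,,published estimate
cCSFOR,Cost of major CSF leak,15818,,published estimate
cMarkov1,Annual cost of Markov health state 1,1167,1167,published estimate
cMarkov2,Annual cost of Markov health state 2,1408,1408,published estimate
cMarkov3,Annual cost of Markov health state 3,1649,1649,published estimate
cMarkov4,Annual cost of Markov health state 4,1890,1890,published estimate
cMarkov5,Annual cost of Markov health state 5,2131,2131,published estimate
cMarkov6,Annual cost of Markov health state 6,2372,2372,published estimate
cMarkov7,Annual cost of Markov health state 7,2613,2613,published estimate
cMarkov8,Annual cost of Markov health state 8,2854,2854,published estimate
cMarkov9,Annual cost of Markov health state 9,3095,3095,published estimate
cMarkov10,Annual cost of Markov health state 10,3336,3336,published estimate
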