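# Base English lexicon for spelling correction of VA narratives.
# Replaceable resource: one lowercase word form per line.
able
accident
ache
aching
admitted
advised
afternoon
age
ago
alcohol
alive
ambulance
anemia
ankle
appetite
arm
arms
asleep
asthma
ate
attack
attended
aunt
away
baby
back
bad
bath
bed
bedridden
began
begin
behavior
belly
better
birth
bite
bitten
black
bleeding
blood
blue
body
boil
bone
bones
born
bottle
bowel
boy
brain
breath
breathe
breathing
breathless
breathlessness
brother
brought
burn
burned
burning
burns
bus
called
car
care
carried
case
caste
cattle
center
certificate
checked
checkup
chest
chew
child
children
chill
chills
chronic
clinic
close
closed
cold
collapsed
color
coma
complained
complaint
complete
condition
confused
conscious
consciousness
constant
consulted
consumed
continued
control
cough
coughing
cousin
cried
cry
crying
cured
cut
daughter
day
days
dead
death
deceased
delivered
delivery
diagnosed
died
discharged
disease
dizziness
dizzy
doctor
doctors
dog
dose
drink
drinking
drowned
drug
drugs
dry
due
dying
ear
earlier
early
eat
eating
eight
elder
evening
examined
expired
eye
eyes
face
failed
failure
faint
fainted
fall
family
farm
fast
father
feeding
feel
feeling
feet
fell
felt
female
field
fifteen
fight
finger
fire
first
fit
fits
five
fluid
food
foot
four
fourth
fracture
gas
girl
given
good
grand
grew
growth
hand
hands
hanged
hanging
happened
hard
head
headache
health
heart
heavy
herself
high
hit
home
hospital
hot
hour
hours
house
hurt
husband
ill
illness
improve
improved
infection
injection
injured
injuries
injury
intake
iron
itching
kept
kidney
knee
labor
labour
last
late
later
left
leg
legs
level
liquid
little
liver
local
long
loose
loss
lost
low
lump
lungs
lying
machine
male
man
marriage
married
medical
medicine
medicines
member
mild
milk
minutes
moment
money
month
months
morning
mother
motion
motions
mouth
moved
movement
nausea
neck
needle
neighbor
nephew
nerve
night
nine
normal
nose
nothing
noticed
often
old
one
operated
operation
pain
painful
pains
pale
paralysis
paralyzed
passed
patient
people
period
person
phlegm
pill
pills
place
poison
pond
poor
pregnant
prescribed
pressure
private
problem
problems
pulse
pus
quickly
rain
rash
reached
ready
recover
recovered
red
referred
refused
relative
relatives
relief
remained
remedy
report
reports
rest
result
returned
rice
right
river
road
room
rope
rural
sad
scan
school
second
seen
seizure
serious
seven
severe
shift
shifted
shivering
shock
shop
shortness
shoulder
shown
sick
sickness
side
sister
sitting
six
skin
sleep
sleeping
slept
slight
slipped
slowly
small
smoke
smoking
snake
son
sore
speak
speech
spell
spine
spit
spitting
spots
sputum
started
state
station
stiff
stomach
stool
stools
stopped
stove
stroke
strong
stumbled
sudden
suddenly
suffered
suffering
sugar
suicide
surgery
swallow
sweating
swelling
swollen
symptom
symptoms
taken
taking
talk
tea
teeth
temperature
ten
test
tests
therapy
thin
third
thirst
three
throat
tied
time
times
tired
tongue
took
tooth
train
travel
treated
treatment
tree
tried
trouble
truck
turned
twelve
twenty
two
uncle
unconscious
unknown
unwell
urinate
urination
urine
used
usual
village
violent
visit
visited
vomit
vomited
vomiting
walk
walking
wall
ward
water
watery
way
weak
weakness
week
weeks
weight
well
wheezing
white
wife
without
woke
woman
work
worker
working
worse
worsened
wound
year
years
yellow
yellowish
young
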